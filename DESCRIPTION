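Package: retinascreen
Title: Screening of Non-Proliferative Diabetic Retinopathy from Color Fundus Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of retinal main structures (blood vessels, optic disc,
    macula) and early lesions (microaneurysms, hemorrhages, hard exudates) in
    color fundus photographs, with image-level grading of non-proliferative
    diabetic retinopathy severity and back-projection of planar detections onto
    a spherical eye model. Vessels and microaneurysms are detected with phase
    congruency computed from a log-Gabor filter bank after contrast-limited
    adaptive histogram equalization and coupled anisotropic diffusion
    filtering; the optic disc is located by least-squares parabola fitting of
    the vascular arcade skeleton followed by a windowed luminance response and
    circular Hough segmentation; hemorrhages are extracted by background
    subtraction, k-means clustering, adaptive region growing and a two-stage
    support-vector-machine cascade; hard exudates by morphological
    reconstruction and Kirsch compass edges. A synthetic fundus phantom
    generator with exact ground truth makes every stage testable without
    clinical image databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    e1071,
    jsonlite,
    Rcpp,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
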