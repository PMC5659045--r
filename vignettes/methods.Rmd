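---
title: "Methods: screening non-proliferative diabetic retinopathy from fundus photographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening non-proliferative diabetic retinopathy from fundus photographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the problem

Non-proliferative diabetic retinopathy (NPDR) shows itself in color fundus
photographs through three early lesion classes: microaneurysms (MAs, dot-like
dark capillary outpouchings of 1–3 px radius at DRIVE-like resolution),
intraretinal hemorrhages (larger dark blobs), and hard exudates (bright,
sharply delimited lipid deposits). `retinascreen` detects the retinal main
structures (vessel tree, optic disc, macula), detects those three lesion
classes, grades the image, and back-projects all detections onto a spherical
eye model. Every stage operates on the green channel of the RGB image, where
vessel and lesion contrast is highest, with all gray processing in float
\[0,1\] (thresholds quoted on the 8-bit scale, such as the region-growing
cut-off of 100, are divided by 255). Pixel coordinates are (row, col) with
row 1 at the top; centers are reported as floats.

# Preprocessing

Contrast is first equalized with CLAHE (8×8 tiles, clip limit 2; the tile
grid and clip limit are not dictated by the method itself and are exposed in
the configuration). Because tile-wise equalization amplifies noise, the
result `M` is then smoothed by a pair of coupled evolution equations:

* the filtered field `u` moves by mean-curvature flow gated by
  `g(|∇v|) = 1/(1 + l |∇v|²)` and is pulled back toward `M` with weight
  `1 − g`;
* the correction field `v` moves by curvature flow weighted by a decaying
  schedule `a_n` (40 for iterations 1–9, −0.7 per iteration through 55,
  halved each iteration after) and is pulled toward `u` with coupling
  `b = 0.02`.

Where `v` is smooth the gate opens and `u` undergoes pure curvature
smoothing; across strong edges of `v` the fidelity term dominates, which is
what preserves vessel boundaries. Numerical choices: explicit Euler with time
step 0.1, central differences, curvature regularized by `ε = 1e−6`, both
fields clamped to \[0,1\], 60 iterations by default (the schedule has
collapsed by then). The early schedule values make the `v` equation stiff for
an explicit scheme, so the curvature update of `v` is magnitude-limited to
0.05 per pixel per iteration — a gradient limiter, not a change of the flow's
direction. `l` defaults to 0.01 (only "small" is prescribed by the method).
Pixels outside the camera aperture are frozen. The iteration is implemented
in C++ because it visits every pixel 60 times.

# Phase congruency

Vessels and MAs are low-contrast structures, so they are detected with phase
congruency (PC) rather than gradients: PC marks points where the local
Fourier components are maximally in phase and is invariant to brightness and
contrast changes. The implementation uses a log-Gabor bank with 8
orientations and 3 scales, adjacent wavelengths separated by a factor 1.6,
bandwidth ratio 0.55, and

PC = Σ_o W_o ⌊E_o − T_o⌋ / (Σ_o Σ_s A_so + ε),  ε = 1e−5,

with the positive part ⌊·⌋ (the standard reading), local energy accumulated
over scales per orientation, a Rayleigh-model noise floor `T_o` estimated
from the median smallest-scale amplitude (multiplier `k`, default 3), and a
sigmoid frequency-spread weight `W_o`. The noise floor estimator and `W_o`
follow the standard PC construction because the defining account names but
does not define them. Images are mirror-padded to FFT-friendly sizes; an
exact-circular (no padding) mode exists and is verified against a direct
spatial-convolution oracle in the tests. Because the filters have no DC
response and the noise floor scales with signal amplitude, PC is invariant
under positive affine intensity maps up to the ε terms.

# Vessel segmentation

PC is computed twice — on the raw green channel and on the preprocessed
image — and the two maps are multiplied pixel-wise: structure present in
both survives, one-sided noise is suppressed. The product is renormalized,
binarized with the isodata (iterative) threshold, cleaned by a 1 px opening
(the thresholded PC response carries a thin halo around the vessel core),
area-filtered (30 px minimum at 565 px width, scaled with the squared width
ratio), and finally cleaned of compact blob components: vessels are tubes,
so components whose boundary²/(4π·area) falls below 3 and whose area is not
arcade-sized are removed — dark lesions also produce phase congruency and
would otherwise contaminate both the mask and the hemorrhage stage that
subtracts it. The minimum filter wavelength for this stage is 5 px at 565 px
width: at 3 px the smallest-scale filters respond to the two edges of a
5–7 px arcade vessel separately and the binarized mask fragments into double
ridges.

# Optic disc

The main arcade is modeled as a parabola. The skeleton of the main vessels
(bottom-hat transform with a disc of radius W/40, isodata threshold,
intersection with the vessel mask, morphological closing, Zhang–Suen
thinning, spur pruning, largest component) is fitted in both orientations —
row as a quadratic in column and vice versa, by least squares on
centered/scaled abscissae — and the lower-residual fit wins. The OD center
is then the maximum of the windowed luminance response `R = mean(A) · var(I)`
(A of CIE Lab, I = (R+G+B)/3 of HSI, population variance) over a circular
window of diameter W/6 (the prescribed range is W/7–W/5) scanning a square
region of side W/3 around the parabola vertex at stride diameter/4, with a
half-stride refinement. Window centers are constrained so the window lies
inside the camera aperture — the aperture rim otherwise dominates the
variance factor. The boundary is segmented by a circular Hough transform on
gradient edges of the green channel (σ = 1.5 pre-blur; 90th-percentile edge
selection; radii swept in \[W/14, W/10\]). Each edge pixel casts two votes
along its gradient direction, and the accumulator is pooled 3×3; plain
angle-sampled voting needs more samples than rim pixels and was noise-limited.
A normalized peak below 0.15 (about half of what a clean disc boundary
attains under realistic noise) flags the segmentation low-confidence and
falls back to a default-radius disc at the located center.

# Macula

The macula is the darkest, near-circular region; its profile is close to an
inverted Gaussian. Candidates are the regional minima of the coarse
approximation of an undecimated quadratic-spline dyadic wavelet
decomposition (the à-trous scheme with scaling filter {1/8, 3/8, 3/8, 1/8},
4 levels; the half-sample-symmetric filter is applied with alternating
alignment so the net drift cancels). Minima within 1.2 OD radii of the OD
center or near the aperture rim are excluded; the 10 darkest survive.
Each candidate is scored on gray contours: 5 iso-levels between the local
minimum and local median in a window of radius W/20, each contributing
concentricity/circularity of the region containing the candidate. Contours
are evaluated on the level-2 wavelet approximation — on the raw channel,
sensor noise shreds the iso-contours of the shallow macular depression. The
final score multiplies the contour score by the candidate's normalized
coarse-scale darkness (mapped to \[0.2, 1\]): the macula is *both* darkest
and concentric, and either cue alone is fooled by a deep, round hemorrhage.
This makes localization independent of the OD position beyond the exclusion
zone, which the tests verify by moving a synthetic OD 50 px.

# Microaneurysms

Candidates are local maxima of PC computed on the inverted green channel at
small scales (minimum wavelength 3 px over a σ = 1 px blur — at these scales
the chief competitor of a dot lesion is single-pixel noise), thresholded by
isodata, excluded on the dilated vessel mask and the OD, and capped at the
100 strongest peaks. Each candidate is scored on 8 cross-section profiles
(0°, 22°, 45°, 66°, 90°, 111°, 135°, 156°; the non-uniform list is used
verbatim) of length W = 15 sampled nearest-neighbor through the center.
Per direction, 7 binary criteria are evaluated on the lightly smoothed
profile ((1,2,3,2,1)/9 — all 8 profiles share the center sample, so an
unsmoothed noise spike mimics an MA in every direction): peak existence,
relative prominence ≥ 0.5 of the profile range, width at half prominence in
\[2, W/2\], two flat baselines (3-point slope ≤ 0.02 of range per px),
centering within ±2 px, and left/right symmetry within a factor 2. The
score is the number of satisfied criteria, 0–56; an ideal dot scores 56, a
flat window 0. Thresholds are relative to the profile range so the score is
gain-invariant. The default acceptance is score ≥ 35, calibrated on phantom
score distributions (planted MAs score 36–46, background peaks rarely exceed
33). The cited score band \[20, 30\] originates from a method with a
different score scale; it remains selectable
(`ma_accept_mode = "window"`) but would reject ideal dots on this scale.

# Hemorrhages

The enhanced image minus a large median background (80 px kernel at 1500 px
width, scaled linearly, forced odd) carries lesions as negative excursions.
The difference image is clustered by 1-D k-means (K = 5, quantile
initialization, Lloyd iterations to a 1e−6 center shift; the within-cluster
sum of squares is recorded at every iteration and is non-increasing by
construction). Clusters whose center lies below mean − 0.5 sd form the
candidate mask; the dilated vessel mask is subtracted, components losing
more than 80% of their area are dropped entirely. Each candidate seeds an
adaptive region growing on the green channel accepting a pixel iff
`|f − m| < 100/255` and `f < T`, with `m` the running region mean and `T` a
local Otsu threshold over three times the candidate bounding box; growth is
capped at 10× the candidate area and a saturated (leaked) growth falls back
to the clustered candidate itself. Six features — eccentricity, circularity
p²/(4πa) with p the boundary pixel count, the moment-ellipse axis ratio,
and the gray features m_in, m_out (2 px ring), m_d = m_out − m_in — feed a
two-stage SVM cascade (RBF kernels, standardized features, 5-fold CV
reported): stage 1 rejects vessel fragments on the shape features, stage 2
rejects background on the gray features.

# Hard exudates

The background is estimated by opening-by-reconstruction (marker = erosion
with a disc of radius W/30; geodesic dilation under the green channel until
stability), so `B = green − background ≥ 0` isolates bright structures
smaller than the structuring element. Edge strength is the maximum of the 8
Kirsch compass templates, computed on a σ = 1.5 blurred channel (the
compass response to raw sensor noise otherwise floods the threshold).
Regions of `B` above its isodata threshold, closed and hole-filled, become
candidates when their boundary reaches the isodata threshold of the edge
field — exudates must be bright *and* sharp-edged (conjunctive, since both
properties define the lesion); regions touching the OD mask dilated by 0.2
radii are removed. An SVM on shape (circularity, eccentricity), gray
(m_in, m_d) and phase (mean boundary PC — the pipeline's own phase
machinery) features separates exudates from soft bright artifacts.

# Grading

The image grade uses only the lesion classes this system detects: no lesions
→ `no_dr`; MAs only → `mild`; any hemorrhage or exudate → `moderate`;
`severe` requires more than 20 hemorrhages in each of the four quadrants
about the macula (image center as fallback) — the hemorrhage clause of the
clinical 4-2-1 rule; venous beading and IRMA are not detected and therefore
cannot contribute. The grade is monotone in lesion counts and independent of
image resolution.

# Spherical eye model

From the camera working distance `AB`, axial length `BD`, fundus-image
height `EF` and field angle `α`: `EC = EF/2`,
`CD = AB + BD − EC·cot(α/2)` (an error if non-positive),
`ED = √(EC² + CD²)`, `β = atan(EC/CD)`, `R = ED/(2 cos β)`. The imaged
fundus is the cap between the rim chord and the pole; the rim-to-axis angle
at the sphere center is `180° − 2β`. A pixel's radial fraction inside the
aperture maps linearly to the polar angle (equal-angular mapping, the
simplest azimuth-preserving reconstruction of the side-view geometry) with
azimuth preserved, so every projected point satisfies
`(x−g)² + (y−h)² + z² = R²` by construction and the mapping inverts to
within half a pixel. The cap is tessellated on a pixel grid into a
watertight triangle mesh with per-vertex colors (vessels red, hemorrhages
blue, exudates yellow, MAs magenta, centers white) and exported as ASCII
PLY. Defaults when camera parameters are unknown: AB = 25 mm, BD = 24 mm,
α = 45°.

# The fundus phantom

The synthetic generator provides ground truth for every stage: a circular
aperture, a parabolic arcade (widths 2–7 px at 565 px) with branch vessels
radiating from the OD, a bright OD (radius 45 px) within 15 px of the
arcade vertex, an inverse-Gaussian macula 2.6–3 OD diameters from the OD,
MAs (1.5–3 px radius, 15–40% darker), hemorrhages (4–12 px radius unions of
discs with a 1.5 px shoulder), exudates (4–16 px radius, 20–50% brighter,
1 px shoulder), two soft-edged bright illumination artifacts (realistic
distractors and the negative class for the exudate SVM), a radial vignette
(8% at the rim) and additive Gaussian noise (σ = 0.03). Lesion sizes stay
inside the detectors' documented operating ranges (e.g. hemorrhage diameter
below the median-filter kernel) so that regression bounds are informative.
Generation is deterministic given the seed.

Training tables label pre-classifier candidates by ground-truth overlap
(≥ 50% → the overlapped positive class; otherwise vessel fragment or
background by provenance). Vessel removal is skipped during training
extraction so vessel fragments appear among the negatives, mirroring the
class structure of a clinical training set. Because the phantom background
is clean, background negatives for the gray-feature stage are supplemented
by regions grown from random lesion-free seeds, and exudate-SVM negatives
by the soft artifacts' own regions.

What the phantom does **not** emulate: texture of the nerve fiber layer,
central vessel reflexes, pigmentation variation, media opacity, flame
hemorrhages, drusen, or the camera's chromatic response. Green-channel
contrast polarity and scale relations are faithful, so passing the phantom
regression shows the pipeline's machinery is sound — it does not certify
clinical accuracy on real databases, whose published headline numbers
require those images.

# Problem sizes and determinism

The regression study screens ten 584×565 phantoms end to end with
classifiers trained on twelve more (roughly 40/40/90 samples for the
hemorrhage cascade classes and 40/25 for the exudate SVM); the scale was
chosen to keep a complete desk run in minutes while leaving every stage's
bound meaningfully testable. All randomness (phantom content,
cross-validation folds) derives from user-supplied seeds; screening itself
is deterministic given the image and configuration.

# Known limitations

* Vessel masks carry residual halo and miss sub-2 px capillaries; Dice
  against phantom truth is ~0.77–0.82, not a clinical claim.
* MA lesion-level recall is noise-limited near the contrast floor
  (image-level detection is robust across seeds).
* Region growing assumes a locally bimodal window; on uniform windows the
  local Otsu threshold is meaningless and growth is flagged degenerate.
* The Hough confidence threshold and the MA acceptance floor are calibrated
  on phantom statistics; clinical recalibration is expected and both are
  configuration keys.
* The equal-angular cap mapping is one of several defensible readings of
  the side-view geometry; it is exactly invertible, which the tests use.
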