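# Hard-exudate detection: morphological-reconstruction background, Kirsch
# compass edges, OD removal, SVM classification.

# Grayscale reconstruction by dilation (geodesic dilation of the marker
# under the mask to convergence), via alternating raster sweeps in C++.
morph_reconstruct <- function(marker, mask_im) {
  stopifnot(all(marker <= mask_im + 1e-12))
  .reconstruct_cpp(marker, mask_im)
}

#' Bright-structure map by opening-by-reconstruction background estimation
#'
#' The marker is an erosion of the green channel with a disc larger than the
#' vessel width; its morphological reconstruction under the green channel is
#' the background (bright objects smaller than the structuring element are
#' levelled out, everything else is restored exactly). The bright map is
#' `B = green - background >= 0`.
#'
#' @param green Green `channel_image` or matrix.
#' @param se_radius Structuring-element radius in px (default W/30).
#' @return List: `bright` (B matrix, >= 0), `background` (matrix).
#' @export
background_morph <- function(green, se_radius = NULL) {
  g <- ch_data(green)
  if (is.null(se_radius)) se_radius <- max(3L, round(ncol(g) / 30))
  marker <- gerode_mat(g, disc_brush(se_radius))
  bg <- morph_reconstruct(marker, g)
  list(bright = pmax(g - bg, 0), background = bg)
}

#' Kirsch compass edge strength
#'
#' Maximum over the 8 classical 3x3 Kirsch templates (weights 5 and -3) of
#' the convolution response at each pixel.
#'
#' @param ch `channel_image` or matrix.
#' @return Matrix of edge strengths (>= 0 up to filter response sign).
#' @export
kirsch_edges <- function(ch) {
  m <- ch_data(ch)
  base <- c(5, 5, 5, -3, 0, -3, -3, -3, -3)  # row-wise 3x3
  ring_order <- rbind(c(1, 1), c(1, 2), c(1, 3), c(2, 3), c(3, 3), c(3, 2),
                      c(3, 1), c(2, 1))
  tmpl <- matrix(base, 3, 3, byrow = TRUE)
  ring_vals <- tmpl[ring_order]
  out <- matrix(-Inf, nrow(m), ncol(m))
  for (k in 0:7) {
    rot <- matrix(0, 3, 3)
    rot[ring_order] <- ring_vals[((seq_len(8) - 1 + k) %% 8) + 1]
    resp <- ebi_mat(EBImage::filter2(as_image(m), rot,
                                       boundary = "replicate"))
    out <- pmax(out, resp)
  }
  out
}

#' Hard-exudate candidate extraction
#'
#' Bright-map pixels above the isodata threshold are grouped into closed,
#' hole-filled regions; a region is a candidate when the Kirsch edge
#' strength on its boundary reaches the isodata threshold of the edge field
#' (candidates must be both bright and sharp-edged), and is removed when it
#' intersects the optic disc mask dilated by 0.2 radii.
#'
#' @param bright Bright map `B` from [background_morph()].
#' @param edges Kirsch edge field.
#' @param od OD result (list with `mask`, `radius`) or `NULL`.
#' @param fov Optional FOV mask.
#' @param green Green matrix for gray features (defaults to `bright`).
#' @param pc Optional PC map for the phase feature.
#' @return List of candidates, each: `pixels` (n x 2), `features` (named
#'   vector: circularity, eccentricity, m_in, m_d, pc_boundary,
#'   edge_strength).
#' @export
exudate_candidates <- function(bright, edges, od = NULL, fov = NULL,
                               green = NULL, pc = NULL) {
  H <- nrow(bright); W <- ncol(bright)
  if (is.null(green)) green <- bright
  inner <- if (is.null(fov)) matrix(TRUE, H, W) else
    erode_mat(fov, disc_brush(max(3L, round(W / 60))))
  ev <- edges[inner]
  thr_e <- tryCatch(iterative_threshold(ev), error = function(e) Inf)
  bv <- bright[inner]
  thr_b <- tryCatch(iterative_threshold(bv), error = function(e) Inf)
  bmask <- bright >= thr_b & inner
  if (!any(bmask)) return(list())
  bmask <- fill_holes(ebi_mat(EBImage::closing(as_image(bmask * 1),
                                               disc_brush(2L))) > 0.5)
  bmask <- bmask & inner
  od_zone <- if (!is.null(od))
    dilate_mat(od$mask, disc_brush(max(1L, round(0.2 * od$radius))))
  else matrix(FALSE, H, W)
  labels <- label_components(bmask)
  out <- list()
  for (i in seq_len(max(labels))) {
    idx <- which(labels == i, arr.ind = TRUE)
    if (nrow(idx) < 4) next
    if (any(od_zone[idx])) next
    # work in the candidate bounding box (morphology on the full image is
    # needless for small regions)
    r0 <- max(1L, min(idx[, 1]) - 4L); r1 <- min(H, max(idx[, 1]) + 4L)
    c0 <- max(1L, min(idx[, 2]) - 4L); c1 <- min(W, max(idx[, 2]) + 4L)
    sub <- matrix(FALSE, r1 - r0 + 1L, c1 - c0 + 1L)
    sub[cbind(idx[, 1] - r0 + 1L, idx[, 2] - c0 + 1L)] <- TRUE
    g_sub <- green[r0:r1, c0:c1]
    e_sub <- edges[r0:r1, c0:c1]
    ring <- dilate_mat(sub, disc_brush(2L)) & !sub
    bnd <- sub & !erode_mat(sub, disc_brush(1L))
    if (max(e_sub[bnd]) < thr_e) next   # bright but soft-edged: not sharp
    fv <- extract_features(idx, green)
    feats <- c(circularity = unname(fv["circularity"]),
               eccentricity = unname(fv["eccentricity"]),
               m_in = mean(g_sub[sub]),
               m_d = mean(g_sub[ring]) - mean(g_sub[sub]),
               pc_boundary = if (is.null(pc)) NA_real_ else
                 mean(pc[r0:r1, c0:c1][bnd]),
               edge_strength = max(e_sub[bnd]))
    out[[length(out) + 1]] <- list(pixels = idx, features = feats,
                                   centroid = c(mean(idx[, 1]), mean(idx[, 2])))
  }
  out
}

#' Train the exudate SVM
#'
#' Single-stage RBF SVM on shape (circularity, eccentricity), gray
#' (m_in, m_d) and phase (mean boundary PC) features, separating exudates
#' from bright artifacts.
#'
#' @param samples Data frame with `label` (`"exudate"` / `"artifact"`) and
#'   the feature columns.
#' @param seed RNG seed for the cross-validation folds.
#' @return An `exudate_model` list: `fit`, `cv_accuracy`, `features`.
#' @export
train_exudate_svm <- function(samples, seed = 1) {
  feats <- c("circularity", "eccentricity", "m_in", "m_d", "pc_boundary")
  stopifnot(is.data.frame(samples), all(c("label", feats) %in% names(samples)))
  if (length(unique(samples$label)) < 2 || any(table(samples$label) < 5))
    stop("exudate SVM needs >= 2 classes with >= 5 samples")
  set.seed(seed)
  fit <- e1071::svm(x = as.matrix(samples[, feats]),
                    y = factor(samples$label == "exudate",
                               levels = c(FALSE, TRUE)),
                    kernel = "radial", scale = TRUE, cross = 5)
  structure(list(fit = fit, cv_accuracy = fit$tot.accuracy / 100,
                 features = feats), class = "exudate_model")
}

#' Classify exudate candidates
#' @param cands Candidate list from [exudate_candidates()].
#' @param model A trained `exudate_model`.
#' @return Logical vector of accepted candidates.
#' @export
classify_exudates <- function(cands, model) {
  if (!inherits(model, "exudate_model")) stop("untrained exudate model")
  if (!length(cands)) return(logical(0))
  X <- do.call(rbind, lapply(cands, function(cd) cd$features[model$features]))
  stats::predict(model$fit, X) == "TRUE"
}

#' Hard-exudate detection stage
#'
#' @param green Green `channel_image`.
#' @param od OD result or `NULL`.
#' @param cfg Configuration list.
#' @param fov Optional FOV mask.
#' @param pc Optional PC map (phase feature); computed from the green
#'   channel when `NULL`.
#' @param model Optional trained `exudate_model`; without it all candidates
#'   are returned unclassified.
#' @return List: `lesions` (accepted candidates), `candidates` (all),
#'   `bright`, `edges`.
#' @export
detect_exudates <- function(green, od = NULL, cfg = default_config(),
                            fov = NULL, pc = NULL, model = NULL) {
  g <- ch_data(green)
  se <- max(3L, round(ncol(g) * cfg$exu_se_frac))
  bm <- background_morph(g, se)
  # edges from a lightly denoised channel: the compass response to raw
  # sensor noise otherwise floods the edge threshold
  gs <- ebi_mat(EBImage::gblur(as_image(g), sigma = 1.5))
  edges <- kirsch_edges(gs)
  if (is.null(pc)) {
    pars <- pc_params(n_orient = cfg$pc_orientations, n_scale = cfg$pc_scales,
                      wavelength_min = max(2, cfg$vessel_lambda_min *
                                             ncol(g) / cfg$vessel_ref_width),
                      scale_factor = cfg$pc_scale_factor,
                      epsilon = cfg$pc_epsilon, noise_k = cfg$pc_noise_k,
                      sigma_onf = cfg$pc_sigma_onf)
    pc <- phase_congruency(g, pars)
  }
  cands <- exudate_candidates(bm$bright, edges, od = od, fov = fov,
                              green = g, pc = pc)
  keep <- rep(TRUE, length(cands))
  if (!is.null(model) && length(cands)) keep <- classify_exudates(cands, model)
  list(lesions = cands[keep], candidates = cands, bright = bm$bright,
       edges = edges)
}
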