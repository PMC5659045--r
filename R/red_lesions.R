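# Microaneurysm and hemorrhage detection.

#' Microaneurysm candidate extraction
#'
#' MAs appear as small dark dots: a phase-congruency map of the inverted
#' green channel at small scales (minimum wavelength 2 px) is thresholded by
#' the isodata rule; local maxima of the map outside the (dilated) vessel
#' mask and the optic-disc mask are the candidate centers.
#'
#' @param green Green `channel_image` or matrix.
#' @param vessels Logical vessel mask (or `NULL`).
#' @param od_mask Logical OD mask (or `NULL`).
#' @param cfg Configuration list.
#' @param fov Optional FOV mask.
#' @param cap Maximum number of candidates, strongest PC peaks first
#'   (default `cfg$ma_candidate_cap`).
#' @return n x 2 matrix of candidate (row, col) centers (may have 0 rows).
#' @export
ma_candidates <- function(green, vessels = NULL, od_mask = NULL,
                          cfg = default_config(), fov = NULL,
                          cap = cfg$ma_candidate_cap) {
  g <- ch_data(green)
  pars <- pc_params(n_orient = cfg$pc_orientations, n_scale = cfg$pc_scales,
                    wavelength_min = cfg$ma_lambda_min,
                    scale_factor = cfg$pc_scale_factor,
                    epsilon = cfg$pc_epsilon, noise_k = cfg$ma_noise_k,
                    sigma_onf = cfg$pc_sigma_onf)
  # a light blur before the small-scale filters: single-pixel noise is the
  # main competitor of dot lesions at these wavelengths
  gb <- ebi_mat(EBImage::gblur(as_image(g), sigma = 1))
  pc <- phase_congruency(1 - gb, pars)
  allow <- matrix(TRUE, nrow(g), ncol(g))
  if (!is.null(fov))
    allow <- allow & erode_mat(fov, disc_brush(max(3L, round(ncol(g) / 60))))
  if (!is.null(vessels)) allow <- allow & !dilate_mat(vessels, disc_brush(2L))
  if (!is.null(od_mask)) allow <- allow & !od_mask
  pc[!allow] <- 0
  if (max(pc) == 0) return(matrix(numeric(0), 0, 2))
  thr <- tryCatch(iterative_threshold(pc[allow]), error = function(e) Inf)
  peaks <- pc >= pmax(thr, 1e-3) & pc >= gdilate_mat(pc, disc_brush(3L)) - 1e-12
  if (!any(peaks)) return(matrix(numeric(0), 0, 2))
  labels <- label_components(peaks)
  n <- max(labels)
  ctr <- t(vapply(seq_len(n), function(i) {
    idx <- which(labels == i, arr.ind = TRUE)
    # darkest pixel of the green channel within the peak plateau
    j <- which.min(g[idx])
    c(as.numeric(idx[j, ]), max(pc[idx]))
  }, numeric(3)))
  # strongest peaks first; the profile classifier sees at most `cap`
  ctr <- ctr[order(-ctr[, 3]), , drop = FALSE]
  ctr <- utils::head(ctr, cap)[, 1:2, drop = FALSE]
  colnames(ctr) <- c("row", "col")
  ctr
}

#' Cross-section intensity profiles of an MA candidate
#'
#' Scans the inverted green channel along 8 directions (0, 22, 45, 66, 90,
#' 111, 135, 156 degrees) through the candidate center, sampling `W` points
#' by nearest neighbor.
#'
#' @param green_inv Inverted green channel matrix (lesions bright).
#' @param center Candidate (row, col).
#' @param W Window size, odd (default 15).
#' @return A `ma_profiles` object: list with `profiles` (8 x W matrix, one
#'   row per direction) and `angles_deg`. `NULL` if the window would be
#'   clipped by the image border (such candidates are discarded).
#' @export
cross_section_profiles <- function(green_inv, center, W = 15) {
  stopifnot(W %% 2 == 1)
  H <- nrow(green_inv); Wd <- ncol(green_inv)
  half <- (W - 1) / 2
  angles <- c(0, 22, 45, 66, 90, 111, 135, 156)
  t_seq <- -half:half
  prof <- matrix(NA_real_, length(angles), W)
  for (i in seq_along(angles)) {
    th <- angles[i] * pi / 180
    rows <- round(center[1] - t_seq * sin(th))
    cols <- round(center[2] + t_seq * cos(th))
    if (any(rows < 1 | rows > H | cols < 1 | cols > Wd)) return(NULL)
    prof[i, ] <- green_inv[cbind(rows, cols)]
  }
  structure(list(profiles = prof, angles_deg = angles, W = W),
            class = "ma_profiles")
}

# The 7 profile criteria for one direction; thresholds are relative to the
# profile's own range, so the score is invariant to intensity gain. The
# profile is lightly smoothed first: all 8 directional profiles share the
# center sample, so an unsmoothed single-pixel noise spike would mimic a
# microaneurysm in every direction.
profile_hits <- function(p, h_min = 0.5, s_max = 0.02) {
  W <- length(p)
  ctr <- (W + 1) / 2
  sm <- stats::filter(p, c(1, 2, 3, 2, 1) / 9)
  ok <- !is.na(sm)
  p[ok] <- sm[ok]
  rng <- max(p) - min(p)
  if (rng < 1e-9) return(0L)
  q <- (p - min(p)) / rng
  ipk <- (ctr - 2):(ctr + 2)
  i_star <- ipk[which.max(q[ipk])]
  pk <- q[i_star]
  bl <- mean(q[1:3]); br <- mean(q[(W - 2):W])
  hits <- 0L
  # 1: a central peak exists above both baselines
  c1 <- pk > bl && pk > br
  hits <- hits + c1
  prom <- pk - max(bl, br)
  # 2: prominence above both shoulders
  hits <- hits + (c1 && prom >= h_min)
  # 3: width at half prominence within [2, W/2] (a 1 px spike is not a dot)
  if (c1 && prom > 0) {
    half_lv <- pk - prom / 2
    l <- i_star; while (l > 1 && q[l - 1] >= half_lv) l <- l - 1
    r <- i_star; while (r < W && q[r + 1] >= half_lv) r <- r + 1
    wdt <- r - l + 1
    hits <- hits + (wdt >= 2 && wdt <= W / 2)
  }
  # 4 & 5: flat left and right baselines (normalized slope per px over the
  # outer 3 samples; further in, even an ideal dot's tail has visible slope)
  sl <- abs(stats::coef(stats::lm.fit(cbind(1, 1:3), q[1:3]))[2])
  sr <- abs(stats::coef(stats::lm.fit(cbind(1, 1:3), q[(W - 2):W]))[2])
  hits <- hits + (sl <= s_max) + (sr <= s_max)
  # 6: global maximum centered within +/- 2 px
  hits <- hits + (abs(which.max(q) - ctr) <= 2)
  # 7: left/right prominence symmetry within a factor 2
  if (c1 && pk - br > 1e-9) {
    ratio <- (pk - bl) / (pk - br)
    hits <- hits + (ratio >= 0.5 && ratio <= 2)
  }
  as.integer(hits)
}

#' MA profile score
#'
#' Evaluates 7 peak criteria (existence, prominence, width at half
#' prominence, two baseline slopes, centering, symmetry) on each of the 8
#' directional profiles; the score is the total number of satisfied
#' criteria, 0..56. An ideal radially symmetric dot scores 56; a flat window
#' scores 0; a vessel-like ridge fails the along-ridge directions.
#'
#' @param ps A `ma_profiles` object.
#' @param h_min Minimum relative prominence (default 0.5 of the profile
#'   range).
#' @param s_max Maximum relative baseline slope per px (default 0.02).
#' @return Integer score in \[0, 56\].
#' @export
ma_score <- function(ps, h_min = 0.5, s_max = 0.02) {
  stopifnot(inherits(ps, "ma_profiles"))
  sum(vapply(seq_len(nrow(ps$profiles)), function(i)
    profile_hits(ps$profiles[i, ], h_min, s_max), integer(1)))
}

#' Microaneurysm detection stage
#'
#' Extracts candidates, scores their cross-section profiles, and accepts
#' according to the configured rule: `ma_accept_mode = "ge"` accepts scores
#' at or above `ma_accept_min` (default); `"window"` accepts scores inside
#' `ma_score_window` (the closed band of the source method's score scale).
#'
#' @param green Green `channel_image`.
#' @param vessels Vessel mask or `NULL`.
#' @param od_mask OD mask or `NULL`.
#' @param cfg Configuration list.
#' @param fov Optional FOV mask.
#' @return List: `centers` (n x 2), `scores` (length n), `candidates` (all
#'   scored candidates with their scores).
#' @export
detect_mas <- function(green, vessels = NULL, od_mask = NULL,
                       cfg = default_config(), fov = NULL) {
  g <- ch_data(green)
  cand <- ma_candidates(green, vessels, od_mask, cfg, fov)
  if (!nrow(cand))
    return(list(centers = cand, scores = integer(0),
                candidates = cbind(cand, score = numeric(0))))
  inv <- 1 - g
  scores <- rep(NA_integer_, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ps <- cross_section_profiles(inv, cand[i, ], W = cfg$ma_window)
    if (!is.null(ps)) scores[i] <- ma_score(ps, cfg$ma_h_min, cfg$ma_s_max)
  }
  keep_sc <- !is.na(scores)
  cand <- cand[keep_sc, , drop = FALSE]; scores <- scores[keep_sc]
  acc <- if (identical(cfg$ma_accept_mode, "window")) {
    scores >= cfg$ma_score_window[1] & scores <= cfg$ma_score_window[2]
  } else {
    scores >= cfg$ma_accept_min
  }
  list(centers = cand[acc, , drop = FALSE], scores = scores[acc],
       candidates = cbind(cand, score = scores))
}

#' Hemorrhage background subtraction
#'
#' A large median filter estimates the slowly varying background of the
#' enhanced image; the difference `enhanced - background` carries lesions as
#' negative excursions. The kernel is 80 px at a 1500 px image width, scaled
#' linearly and forced odd.
#'
#' @param enhanced Enhanced `channel_image` or matrix.
#' @param cfg Configuration list.
#' @return A `channel_image` with `domain = "difference"`.
#' @export
hemorrhage_background <- function(enhanced, cfg = default_config()) {
  e <- ch_data(enhanced)
  k <- round(cfg$hem_median_kernel * ncol(e) / cfg$hem_median_ref_width)
  k <- max(3L, as.integer(k)); if (k %% 2L == 0L) k <- k + 1L
  bg <- ebi_mat(EBImage::medianFilter(as_image(e), size = (k - 1L) %/% 2L))
  channel_image(e - bg, "difference")
}

#' One-dimensional k-means (Lloyd) on pixel intensities
#'
#' Quantile-initialized Lloyd iterations until the maximum center shift is
#' below 1e-6. The within-cluster sum of squares is recorded at every
#' iteration and is non-increasing by construction of the two Lloyd steps.
#'
#' @param D `channel_image` (difference) or numeric matrix/vector.
#' @param K Number of clusters (default 5; reduced with a warning when there
#'   are fewer distinct values).
#' @param mask Optional logical mask restricting the clustered pixels.
#' @return List: `centers` (sorted), `labels` (matrix of cluster indices, 0
#'   outside mask), `objective` (final E), `objective_trace` (E per
#'   iteration), `K`.
#' @export
kmeans_segment <- function(D, K = 5, mask = NULL) {
  d <- ch_data(D)
  vals <- if (is.null(mask)) as.numeric(d) else as.numeric(d[mask])
  nuniq <- length(unique(vals))
  if (nuniq < K) {
    warning("fewer distinct values than K; reducing K to ", nuniq)
    K <- nuniq
  }
  stopifnot(K >= 1)
  centers <- as.numeric(stats::quantile(vals, (seq_len(K) - 0.5) / K,
                                        names = FALSE, type = 7))
  centers <- sort(centers)
  trace <- numeric(0)
  assign_lab <- function(centers) {
    mids <- (centers[-1] + centers[-length(centers)]) / 2
    findInterval(vals, mids) + 1L
  }
  lab <- assign_lab(centers)
  for (it in 1:500) {
    E <- sum((vals - centers[lab])^2)
    trace <- c(trace, E)
    new_centers <- vapply(seq_len(K), function(i) {
      xi <- vals[lab == i]
      if (length(xi)) mean(xi) else centers[i]
    }, numeric(1))
    new_centers <- sort(new_centers)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    lab <- assign_lab(centers)
    if (shift < 1e-6) break
  }
  trace <- c(trace, sum((vals - centers[lab])^2))
  labels <- matrix(0L, nrow(d), ncol(d))
  if (is.null(mask)) labels[] <- lab else labels[mask] <- lab
  list(centers = centers, labels = labels, objective = trace[length(trace)],
       objective_trace = trace, K = K)
}

#' Hemorrhage candidate mask from the k-means clustering
#'
#' Candidate pixels belong to the clusters whose center lies below
#' `mean - 0.5 sd` of the clustered values (the darkest clusters of the
#' difference image).
#'
#' @param km Result of [kmeans_segment()].
#' @param D The clustered difference image (for the global statistics).
#' @param mask Optional mask used during clustering.
#' @return Logical candidate mask.
#' @export
dark_cluster_mask <- function(km, D, mask = NULL) {
  d <- ch_data(D)
  vals <- if (is.null(mask)) as.numeric(d) else as.numeric(d[mask])
  cut <- mean(vals) - 0.5 * stats::sd(vals)
  dark <- which(km$centers < cut)
  matrix(km$labels %in% dark & km$labels > 0L, nrow(d), ncol(d))
}

#' Remove vessel pixels from a candidate mask
#'
#' The vessel mask is dilated by 2 px and subtracted; candidate components
#' losing more than 80 percent of their area are dropped entirely.
#'
#' @param cands Candidate logical mask.
#' @param vessels Vessel logical mask.
#' @return Cleaned logical mask.
#' @export
remove_vessels <- function(cands, vessels) {
  stopifnot(all(dim(cands) == dim(vessels)))
  vd <- dilate_mat(vessels, disc_brush(2L))
  labels <- label_components(cands)
  if (max(labels) == 0L) return(cands & !vd)
  keep <- cands & !vd
  for (i in seq_len(max(labels))) {
    comp <- labels == i
    if (sum(comp & keep) / sum(comp) < 0.2) keep[comp] <- FALSE
  }
  keep
}

#' Adaptive region growing from a candidate centroid
#'
#' 8-connected flood from the seed accepting a pixel iff
#' `|f - m| < T0` and `f < T`, where `m` is the running mean of the grown
#' region, `T0` the fixed cut-off (100 on the 8-bit scale, 100/255 here) and
#' `T` an Otsu threshold computed in a local window of 3 times the candidate
#' bounding box. Growth is capped at `cap` pixels.
#'
#' @param green Green `channel_image` or matrix.
#' @param seed Seed (row, col).
#' @param T0 Running-mean cut-off (default 100/255).
#' @param T_otsu Otsu threshold; computed from `window` when `NULL`.
#' @param window Optional (r0, r1, c0, c1) local window for Otsu.
#' @param cap Maximum region size in px (default 500).
#' @return n x 2 matrix of region (row, col) pixels (at least the seed if it
#'   satisfies its own criterion, else just the seed flagged by attribute
#'   `degenerate`).
#' @export
region_grow <- function(green, seed, T0 = 100 / 255, T_otsu = NULL,
                        window = NULL, cap = 500) {
  g <- ch_data(green)
  H <- nrow(g); W <- ncol(g)
  seed <- round(seed)
  stopifnot(seed[1] >= 1, seed[1] <= H, seed[2] >= 1, seed[2] <= W)
  if (is.null(T_otsu)) {
    if (is.null(window)) window <- c(1, H, 1, W)
    sub <- g[window[1]:window[2], window[3]:window[4]]
    T_otsu <- as.numeric(EBImage::otsu(as_image(sub), range = c(0, 1)))
  }
  in_region <- matrix(FALSE, H, W)
  f_seed <- g[seed[1], seed[2]]
  if (!(f_seed < T_otsu)) {
    out <- matrix(seed, 1, 2)
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  in_region[seed[1], seed[2]] <- TRUE
  total <- f_seed; n <- 1L
  repeat {
    m <- total / n
    frontier <- dilate_mat(in_region, disc_brush(1L)) & !in_region
    idx <- which(frontier)
    if (!length(idx)) break
    f <- g[idx]
    acc <- abs(f - m) < T0 & f < T_otsu
    if (!any(acc)) break
    take <- idx[acc]
    if (n + length(take) > cap) take <- take[seq_len(cap - n)]
    in_region[take] <- TRUE
    total <- total + sum(g[take]); n <- n + length(take)
    if (n >= cap) break
  }
  out <- which(in_region, arr.ind = TRUE)
  attr(out, "degenerate") <- FALSE
  attr(out, "otsu") <- T_otsu
  out
}

#' Shape and gray features of a lesion candidate region
#'
#' Returns the 6 classification features: eccentricity, circularity
#' `p^2/(4 pi a)` (p = boundary pixel count, a = area), the axis ratio
#' `l1/l2` of the ellipse with matching second-order central moments, the
#' mean gray value inside the region `m_in`, the mean over a 2-px ring
#' around it `m_out`, and the contrast `m_d = m_out - m_in`.
#'
#' @param region n x 2 matrix of region (row, col) pixels, n >= 4.
#' @param green Green `channel_image` or matrix.
#' @return Named numeric vector of the 6 features; attribute `clipped` is
#'   `TRUE` when the ring was clipped by the image border.
#' @export
extract_features <- function(region, green) {
  g <- ch_data(green)
  stopifnot(nrow(region) >= 4)
  H <- nrow(g); W <- ncol(g)
  # all quantities are local: work in the region bounding box
  r0 <- max(1L, min(region[, 1]) - 4L); r1 <- min(H, max(region[, 1]) + 4L)
  c0 <- max(1L, min(region[, 2]) - 4L); c1 <- min(W, max(region[, 2]) + 4L)
  gs <- g[r0:r1, c0:c1, drop = FALSE]
  mask <- matrix(FALSE, nrow(gs), ncol(gs))
  mask[cbind(region[, 1] - r0 + 1L, region[, 2] - c0 + 1L)] <- TRUE
  a <- nrow(region)
  p <- region_perimeter(mask)
  circularity <- p^2 / (4 * pi * a)
  mu_r <- mean(region[, 1]); mu_c <- mean(region[, 2])
  m20 <- mean((region[, 1] - mu_r)^2); m02 <- mean((region[, 2] - mu_c)^2)
  m11 <- mean((region[, 1] - mu_r) * (region[, 2] - mu_c))
  tr <- m20 + m02
  dt <- sqrt(max(0, (m20 - m02)^2 + 4 * m11^2))
  l1 <- (tr + dt) / 2 + 1 / 12   # + pixel self-variance regularizer
  l2 <- (tr - dt) / 2 + 1 / 12
  axis_ratio <- sqrt(l1 / l2)
  eccentricity <- sqrt(max(0, 1 - l2 / l1))
  ring <- dilate_mat(mask, disc_brush(2L)) & !mask
  clipped <- any(region[, 1] %in% c(1L, H)) || any(region[, 2] %in% c(1L, W))
  m_in <- mean(gs[mask]); m_out <- if (any(ring)) mean(gs[ring]) else NA_real_
  out <- c(eccentricity = eccentricity, circularity = circularity,
           axis_ratio = axis_ratio, m_in = m_in, m_out = m_out,
           m_d = m_out - m_in)
  attr(out, "clipped") <- clipped
  out
}

#' Train the two-stage hemorrhage SVM cascade
#'
#' Stage 1 separates hemorrhages from blood-vessel fragments on the shape
#' features (eccentricity, circularity, axis ratio); stage 2 separates
#' hemorrhages from background/laser-residue noise on the gray features
#' (m_in, m_out, m_d). Both are RBF-kernel SVMs on standardized features;
#' 5-fold cross-validation accuracy is reported per stage.
#'
#' @param samples Data frame with a `label` column (one of `"hemorrhage"`,
#'   `"vessel"`, `"background"`) and the 6 feature columns.
#' @param seed RNG seed for the cross-validation folds.
#' @return A `hemorrhage_cascade` list: `stage1`, `stage2` (svm objects),
#'   `cv_accuracy` (length 2).
#' @export
train_cascade <- function(samples, seed = 1) {
  stopifnot(is.data.frame(samples), "label" %in% names(samples))
  shape_f <- c("eccentricity", "circularity", "axis_ratio")
  gray_f <- c("m_in", "m_out", "m_d")
  stopifnot(all(c(shape_f, gray_f) %in% names(samples)))
  s1 <- samples[samples$label %in% c("hemorrhage", "vessel"), ]
  s2 <- samples[samples$label %in% c("hemorrhage", "background"), ]
  for (s in list(s1, s2)) {
    if (length(unique(s$label)) < 2 || any(table(s$label) < 5))
      stop("each cascade stage needs >= 2 classes with >= 5 samples")
  }
  set.seed(seed)
  fit1 <- e1071::svm(x = as.matrix(s1[, shape_f]),
                     y = factor(s1$label == "hemorrhage",
                                levels = c(FALSE, TRUE)),
                     kernel = "radial", scale = TRUE, cross = 5)
  set.seed(seed + 1)
  fit2 <- e1071::svm(x = as.matrix(s2[, gray_f]),
                     y = factor(s2$label == "hemorrhage",
                                levels = c(FALSE, TRUE)),
                     kernel = "radial", scale = TRUE, cross = 5)
  structure(list(stage1 = fit1, stage2 = fit2,
                 cv_accuracy = c(stage1 = fit1$tot.accuracy / 100,
                                 stage2 = fit2$tot.accuracy / 100),
                 shape_features = shape_f, gray_features = gray_f),
            class = "hemorrhage_cascade")
}

#' Classify hemorrhage candidates with the trained cascade
#'
#' @param features Data frame (or matrix) of candidate feature vectors with
#'   the 6 named feature columns.
#' @param cascade A trained `hemorrhage_cascade`.
#' @return Logical vector: `TRUE` for candidates surviving both stages.
#' @export
classify_hemorrhages <- function(features, cascade) {
  if (!inherits(cascade, "hemorrhage_cascade")) stop("untrained cascade model")
  features <- as.data.frame(features)
  if (!nrow(features)) return(logical(0))
  p1 <- stats::predict(cascade$stage1,
                       as.matrix(features[, cascade$shape_features]))
  p2 <- stats::predict(cascade$stage2,
                       as.matrix(features[, cascade$gray_features]))
  p1 == "TRUE" & p2 == "TRUE"
}

#' Hemorrhage detection stage
#'
#' Background subtraction, k-means clustering of the difference image,
#' darkest-cluster candidate extraction, vessel removal, per-candidate
#' region growing on the green channel, feature extraction, and (when a
#' cascade is supplied) SVM classification.
#'
#' @param green Green `channel_image`.
#' @param enhanced Enhanced `channel_image`.
#' @param vessels Vessel logical mask.
#' @param cfg Configuration list.
#' @param fov Optional FOV mask.
#' @param cascade Optional trained `hemorrhage_cascade`; without it all
#'   grown candidates with valid features are returned unclassified.
#' @param od_mask Optional OD logical mask to exclude.
#' @return List: `lesions` (list of region matrices), `centroids`,
#'   `features` (data frame), `candidate_mask`, `kmeans`.
#' @export
detect_hemorrhages <- function(green, enhanced, vessels,
                               cfg = default_config(), fov = NULL,
                               cascade = NULL, od_mask = NULL) {
  g <- ch_data(green)
  D <- hemorrhage_background(enhanced, cfg)
  km <- kmeans_segment(D, K = cfg$hem_kmeans_k, mask = fov)
  cand <- dark_cluster_mask(km, D, mask = fov)
  if (!is.null(fov))
    cand <- cand & erode_mat(fov, disc_brush(max(3L, round(ncol(g) / 60))))
  if (!is.null(od_mask)) cand <- cand & !od_mask
  cand <- remove_vessels(cand, vessels)
  min_area <- max(4, round(10 * (ncol(g) / 565)^2))
  cand <- area_filter(cand, min_area)
  labels <- label_components(cand)
  n <- max(labels)
  lesions <- list(); feats <- list(); cents <- list()
  for (i in seq_len(n)) {
    idx <- which(labels == i, arr.ind = TRUE)
    bb <- c(range(idx[, 1]), range(idx[, 2]))
    hh <- bb[2] - bb[1] + 1; ww <- bb[4] - bb[3] + 1
    win <- c(max(1, bb[1] - hh), min(nrow(g), bb[2] + hh),
             max(1, bb[3] - ww), min(ncol(g), bb[4] + ww))
    seed <- idx[which.min(g[idx]), ]
    cap_i <- max(50, cfg$hem_grow_cap_factor * nrow(idx))
    reg <- region_grow(g, seed, T0 = cfg$hem_region_t0, window = win,
                       cap = cap_i)
    # growth that saturates its cap has leaked into the background; fall
    # back to the clustered candidate itself
    if (nrow(reg) >= cap_i || isTRUE(attr(reg, "degenerate"))) reg <- idx
    if (nrow(reg) < 4) next
    fv <- extract_features(reg, g)
    if (anyNA(fv)) next
    lesions[[length(lesions) + 1]] <- reg
    feats[[length(feats) + 1]] <- fv
    cents[[length(cents) + 1]] <- c(mean(reg[, 1]), mean(reg[, 2]))
  }
  features <- if (length(feats)) as.data.frame(do.call(rbind, feats))
              else as.data.frame(matrix(numeric(0), 0, 6,
                dimnames = list(NULL, c("eccentricity", "circularity",
                  "axis_ratio", "m_in", "m_out", "m_d"))))
  keep <- rep(TRUE, length(lesions))
  if (!is.null(cascade) && length(lesions))
    keep <- classify_hemorrhages(features, cascade)
  list(lesions = lesions[keep],
       centroids = do.call(rbind, cents[keep]) %||% matrix(numeric(0), 0, 2),
       features = features[keep, , drop = FALSE],
       candidate_mask = cand, kmeans = km)
}
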