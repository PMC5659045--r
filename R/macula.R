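# Separable a-trous smoothing with the quadratic-spline scaling filter
# {1/8, 3/8, 3/8, 1/8}; the half-sample-symmetric filter is applied with
# alternating tap alignment per level so the net drift cancels.
qsdwt_smooth <- function(m, levels) {
  h <- c(1, 3, 3, 1) / 8
  a <- m
  for (j in seq_len(levels)) {
    step <- 2^(j - 1)
    offs <- if (j %% 2 == 1) c(-1L, 0L, 1L, 2L) else c(-2L, -1L, 0L, 1L)
    offs <- offs * step
    # rows
    a <- h[1] * shift_mat(a, offs[1], 0L) + h[2] * shift_mat(a, offs[2], 0L) +
         h[3] * shift_mat(a, offs[3], 0L) + h[4] * shift_mat(a, offs[4], 0L)
    # cols
    a <- h[1] * shift_mat(a, 0L, offs[1]) + h[2] * shift_mat(a, 0L, offs[2]) +
         h[3] * shift_mat(a, 0L, offs[3]) + h[4] * shift_mat(a, 0L, offs[4])
  }
  a
}

#' Macular center candidates from a dyadic wavelet decomposition
#'
#' The green channel is smoothed with an undecimated quadratic-spline dyadic
#' wavelet to the coarsest requested scale; regional minima of the coarse
#' approximation are the candidate fovea positions (the macula is the
#' darkest near-circular region). Minima within 1.2 optic-disc radii of the
#' OD center are excluded, the rest ranked by darkness, the top 10 kept.
#'
#' @param green Green `channel_image` or matrix.
#' @param levels Decomposition depth, 2..5 (default 4).
#' @param od Optional list with `center`, `radius` (exclusion zone).
#' @param fov Optional FOV mask; minima must lie well inside it.
#' @param cap Maximum number of candidates (default 10).
#' @return Matrix with columns `row`, `col`, `value` (coarse intensity),
#'   darkest first.
#' @export
qsdwt_candidates <- function(green, levels = 4, od = NULL, fov = NULL,
                             cap = 10) {
  stopifnot(levels >= 2, levels <= 5)
  g <- ch_data(green)
  a <- qsdwt_smooth(g, levels)
  if (diff(range(a)) < 1e-8) stop("no candidates: flat image")
  H <- nrow(a); W <- ncol(a)
  margin <- max(5L, round(W / 20))
  inner <- if (is.null(fov)) matrix(TRUE, H, W) else
    erode_mat(fov, disc_brush(margin))
  loc_min <- a <= gerode_mat(a, disc_brush(5L)) + 1e-12
  loc_min <- loc_min & inner
  if (!is.null(od)) {
    d <- radial_field(H, W, od$center)
    loc_min <- loc_min & d > 1.2 * od$radius
  }
  if (!any(loc_min)) stop("no candidates: no regional minima inside FOV")
  labels <- label_components(loc_min)
  n <- max(labels)
  cand <- t(vapply(seq_len(n), function(i) {
    idx <- which(labels == i, arr.ind = TRUE)
    c(mean(idx[, 1]), mean(idx[, 2]), min(a[idx]))
  }, numeric(3)))
  colnames(cand) <- c("row", "col", "value")
  cand <- cand[order(cand[, "value"]), , drop = FALSE]
  utils::head(cand, cap)
}

#' Gray-contour concentricity score of a candidate fovea
#'
#' Iso-intensity contours are taken at 5 levels between the local minimum
#' and the local median in a window of radius `r_m` around the candidate.
#' Each level contributes `circularity^-1 * concentricity` of the connected
#' region containing the candidate, where circularity is `p^2 / (4 pi a)`
#' (1 for a circle) and concentricity is `1 - centroid offset / r_m`. A
#' radially symmetric dark blob scores near 1; elongated or ragged regions
#' score lower; a constant window scores 0.
#'
#' @param green Green `channel_image` or matrix.
#' @param center Candidate (row, col).
#' @param r_m Window radius in px (default W/20).
#' @param n_levels Number of contour levels (default 5).
#' @return The score (scalar >= 0).
#' @export
contour_score <- function(green, center, r_m = NULL, n_levels = 5) {
  g <- ch_data(green)
  H <- nrow(g); W <- ncol(g)
  if (is.null(r_m)) r_m <- round(W / 20)
  r0 <- round(center[1]) - r_m; r1 <- round(center[1]) + r_m
  c0 <- round(center[2]) - r_m; c1 <- round(center[2]) + r_m
  if (r0 < 1 || c0 < 1 || r1 > H || c1 > W) stop("contour window outside image")
  win <- g[r0:r1, c0:c1]
  lo <- min(win); md <- stats::median(win)
  if (md - lo < 1e-8) return(0)
  ctr <- c(r_m + 1, r_m + 1)
  levels <- lo + (seq_len(n_levels) / (n_levels + 1)) * (md - lo)
  scores <- vapply(levels, function(L) {
    mask <- win <= L
    if (!mask[ctr[1], ctr[2]]) {
      # candidate centroids may fall between minima; use nearest in-mask px
      idx <- which(mask, arr.ind = TRUE)
      if (!nrow(idx)) return(0)
      d2 <- (idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2
      if (min(d2) > 4) return(0)
      ctr <- idx[which.min(d2), ]
    }
    labels <- label_components(mask)
    region <- labels == labels[ctr[1], ctr[2]]
    a <- sum(region)
    if (a < 4) return(0)
    p <- region_perimeter(region)
    circ <- max(1, p^2 / (4 * pi * a))
    cen <- mask_centroid(region)
    conc <- max(0, 1 - sqrt(sum((cen - c(r_m + 1, r_m + 1))^2)) / r_m)
    conc / circ
  }, numeric(1))
  mean(scores)
}

# Count boundary pixels: region pixels with at least one 4-neighbor outside.
region_perimeter <- function(region) {
  inside <- shift_mat(region, 1L, 0L) & shift_mat(region, -1L, 0L) &
    shift_mat(region, 0L, 1L) & shift_mat(region, 0L, -1L)
  # image-border region pixels count as boundary (shift_mat replicates)
  bord <- matrix(FALSE, nrow(region), ncol(region))
  bord[c(1, nrow(region)), ] <- TRUE; bord[, c(1, ncol(region))] <- TRUE
  sum(region & (!inside | bord))
}

#' Locate the macula
#'
#' Scores every wavelet candidate by its gray-contour concentricity
#' ([contour_score()], evaluated on a level-2 wavelet smoothing of the
#' channel so that sensor noise does not shred the iso-contours) weighted by
#' its normalized darkness in the coarse approximation — the macula is the
#' darkest region with near-circular contours, and either cue alone is
#' fooled by deep round hemorrhages.
#'
#' @param green Green `channel_image` or matrix.
#' @param candidates Candidate matrix from [qsdwt_candidates()] (columns
#'   row, col, value).
#' @param r_m Contour window radius (default W/20).
#' @return List: `center` (row, col), `contour_score`, `candidates` (with
#'   `score` and `total` columns appended).
#' @export
locate_macula <- function(green, candidates, r_m = NULL) {
  stopifnot(nrow(candidates) >= 1)
  g <- ch_data(green)
  if (is.null(r_m)) r_m <- round(ncol(g) / 20)
  sm <- qsdwt_smooth(g, 2)
  sc <- apply(candidates, 1, function(cd) {
    tryCatch(contour_score(sm, cd[1:2], r_m = r_m), error = function(e) 0)
  })
  v <- candidates[, "value"]
  dark <- if (nrow(candidates) == 1L || diff(range(v)) < 1e-12)
    rep(1, nrow(candidates))
  else (max(v) - v) / (max(v) - min(v))
  total <- sc * (0.2 + 0.8 * dark)   # darkness-weighted, never fully zeroed
  best <- which.max(total)
  list(center = as.numeric(candidates[best, 1:2]), contour_score = sc[best],
       candidates = cbind(candidates, score = sc, total = total))
}

#' Macula localization stage
#' @param green Green `channel_image`.
#' @param od OD result (list with `center`, `radius`) or `NULL`.
#' @param cfg Configuration list.
#' @param fov Optional FOV mask.
#' @return A macula result as from [locate_macula()].
#' @export
locate_macula_stage <- function(green, od = NULL, cfg = default_config(),
                                fov = NULL) {
  cand <- qsdwt_candidates(green, levels = cfg$macula_levels, od = od,
                           fov = fov, cap = cfg$macula_candidate_cap)
  r_m <- round(ncol(ch_data(green)) * cfg$macula_rm_frac)
  locate_macula(green, cand, r_m = r_m)
}
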