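#' Least-squares parabola fit
#'
#' Fits `l = a0*k^2 + a1*k + a2` through the points by the closed-form
#' normal equations. With `orientation = "y_of_x"` the abscissa `k` is the
#' column and `l` the row (parabola opening up/down); with `"x_of_y"` the
#' roles are swapped (opening left/right).
#'
#' @param points n x 2 matrix of (row, col) pixel coordinates, n >= 3.
#' @param orientation `"y_of_x"` or `"x_of_y"`.
#' @return A `parabola` object: `a0, a1, a2`, `orientation`, `vertex`
#'   ((row, col), `NA` when `a0 = 0`), `residual` (mean squared error).
#' @export
fit_parabola <- function(points, orientation = c("y_of_x", "x_of_y")) {
  orientation <- match.arg(orientation)
  stopifnot(is.matrix(points), ncol(points) == 2, nrow(points) >= 3)
  if (orientation == "y_of_x") { k <- points[, 2]; l <- points[, 1] }
  else                         { k <- points[, 1]; l <- points[, 2] }
  # solve the normal equations on centered/scaled abscissae (conditioning)
  k0 <- mean(k); s <- stats::sd(k)
  if (!is.finite(s) || s < 1e-12) stop("degenerate point set for parabola fit")
  z <- (k - k0) / s
  X <- cbind(1, z, z^2)
  qr_x <- qr(X)
  if (qr_x$rank < 3) stop("degenerate point set for parabola fit")
  bc <- qr.coef(qr_x, l)
  a0 <- unname(bc[3] / s^2)
  a1 <- unname(bc[2] / s - 2 * bc[3] * k0 / s^2)
  a2 <- unname(bc[1] - bc[2] * k0 / s + bc[3] * k0^2 / s^2)
  res <- mean((X %*% bc - l)^2)
  vertex <- if (abs(a0) > 1e-12) {
    ks <- -a1 / (2 * a0); ls <- a0 * ks^2 + a1 * ks + a2
    if (orientation == "y_of_x") c(ls, ks) else c(ks, ls)
  } else c(NA_real_, NA_real_)
  structure(list(a0 = a0, a1 = a1, a2 = a2, orientation = orientation,
                 vertex = vertex, residual = res), class = "parabola")
}

#' Model the vascular arcade and return the better-oriented parabola
#'
#' Fits the skeleton points in both orientations and keeps the fit with the
#' smaller residual; a fit with (numerically) zero curvature has no vertex
#' and is rejected. The vertex is clamped to the image bounds.
#'
#' @param skeleton n x 2 matrix of skeleton (row, col) points.
#' @param shape Image shape (H, W) for vertex clamping.
#' @return A `parabola` object with a finite in-image vertex.
#' @export
choose_arcade_fit <- function(skeleton, shape) {
  stopifnot(nrow(skeleton) >= 3)
  fits <- list()
  for (orient in c("y_of_x", "x_of_y")) {
    f <- tryCatch(fit_parabola(skeleton, orient), error = function(e) NULL)
    if (!is.null(f) && all(is.finite(f$vertex))) fits[[orient]] <- f
  }
  if (!length(fits)) stop("arcade fit degenerate in both orientations")
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "residual"))]]
  best$vertex <- c(min(max(best$vertex[1], 1), shape[1]),
                   min(max(best$vertex[2], 1), shape[2]))
  best
}

# A channel of CIE Lab and I channel of HSI for a fundus image, as matrices.
lab_a_channel <- function(img) {
  d <- dim(img$rgb)
  rgbm <- cbind(as.numeric(img$rgb[, , 1]), as.numeric(img$rgb[, , 2]),
                as.numeric(img$rgb[, , 3]))
  lab <- grDevices::convertColor(rgbm, from = "sRGB", to = "Lab")
  matrix(lab[, 2], d[1], d[2])
}

hsi_i_channel <- function(img) {
  (img$rgb[, , 1] + img$rgb[, , 2] + img$rgb[, , 3]) / 3
}

#' Windowed luminance response of a candidate optic-disc center
#'
#' `R = mean(A) * var(I)` over a circular window: the mean of the CIE Lab A
#' channel times the (population) variance of the HSI intensity channel. The
#' optic disc is both reddish-bright and crossed by dark vessels, so both
#' factors peak there.
#'
#' @param img A `fundus_image`.
#' @param center Window center (row, col).
#' @param diameter Window diameter in px; must fit inside the image.
#' @param A,I Optional precomputed channel matrices (for repeated calls).
#' @return The scalar response.
#' @export
window_response <- function(img, center, diameter, A = NULL, I = NULL) {
  H <- dim(img$rgb)[1]; W <- dim(img$rgb)[2]
  r <- diameter / 2
  if (center[1] - r < 1 || center[1] + r > H ||
      center[2] - r < 1 || center[2] + r > W)
    stop("window outside image")
  if (is.null(A)) A <- lab_a_channel(img)
  if (is.null(I)) I <- hsi_i_channel(img)
  off <- disc_offsets(r)
  rows <- round(center[1]) + off[, 1]; cols <- round(center[2]) + off[, 2]
  idx <- cbind(rows, cols)
  a <- A[idx]; i <- I[idx]
  mean(a) * mean((i - mean(i))^2)
}

# (row, col) offsets of a disc of the given radius around the origin.
disc_offsets <- function(r) {
  ri <- as.integer(floor(r))
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  as.matrix(g[g$dr^2 + g$dc^2 <= r^2, ])
}

#' Locate the optic disc center
#'
#' A square region of interest of side W/3 is centered on the arcade-fit
#' vertex; a circular window (default diameter W/6) scans it on a grid with
#' stride diameter/4 and the maximum of [window_response()] is taken,
#' followed by a half-stride local refinement.
#'
#' @param img A `fundus_image`.
#' @param parabola A `parabola` from [choose_arcade_fit()].
#' @param cfg Configuration list.
#' @return List: `center` (row, col), `response`, `diameter`.
#' @export
locate_od <- function(img, parabola, cfg = default_config()) {
  H <- dim(img$rgb)[1]; W <- dim(img$rgb)[2]
  diameter <- cfg$od_window_frac * W
  r <- diameter / 2
  stride <- max(2L, round(diameter / 4))
  half <- round(W / 6)
  vr <- parabola$vertex[1]; vc <- parabola$vertex[2]
  rows <- seq(max(ceiling(r + 1), vr - half), min(floor(H - r), vr + half), by = stride)
  cols <- seq(max(ceiling(r + 1), vc - half), min(floor(W - r), vc + half), by = stride)
  if (!length(rows) || !length(cols)) {
    warning("empty ROI around vertex; scanning full image")
    rows <- seq(ceiling(r + 1), floor(H - r), by = stride)
    cols <- seq(ceiling(r + 1), floor(W - r), by = stride)
  }
  A <- lab_a_channel(img); I <- hsi_i_channel(img)
  # the window must lie fully inside the FOV or the aperture rim dominates
  # the variance term
  fovdist <- ebi_mat(EBImage::distmap(as_image(img$fov * 1)))
  centers <- as.matrix(expand.grid(row = rows, col = cols))
  cidx <- cbind(pmin(pmax(round(centers[, 1]), 1), H),
                pmin(pmax(round(centers[, 2]), 1), W))
  fov_ok <- fovdist[cidx] > r
  if (any(fov_ok)) centers <- centers[fov_ok, , drop = FALSE]
  resp <- apply(centers, 1, function(ct)
    window_response(img, ct, diameter, A = A, I = I))
  best <- centers[which.max(resp), ]
  # half-stride refinement around the coarse maximum
  fine <- as.matrix(expand.grid(
    row = best[1] + seq(-stride, stride, by = max(2L, stride %/% 2)),
    col = best[2] + seq(-stride, stride, by = max(2L, stride %/% 2))))
  ok <- fine[, 1] - r >= 1 & fine[, 1] + r <= H &
        fine[, 2] - r >= 1 & fine[, 2] + r <= W
  fine <- fine[ok, , drop = FALSE]
  if (nrow(fine)) {
    fidx <- cbind(pmin(pmax(round(fine[, 1]), 1), H),
                  pmin(pmax(round(fine[, 2]), 1), W))
    fine <- fine[fovdist[fidx] > r, , drop = FALSE]
  }
  respf <- if (nrow(fine)) apply(fine, 1, function(ct)
    window_response(img, ct, diameter, A = A, I = I)) else numeric(0)
  if (length(respf) && max(respf) > max(resp)) best <- fine[which.max(respf), ]
  list(center = as.numeric(best), response = max(c(resp, respf)),
       diameter = diameter)
}

#' Segment the optic disc boundary by circular Hough transform
#'
#' Edges of the green channel within 1.5 window diameters of the located
#' center (gradient magnitude above its 90th percentile in the search
#' region) vote for circle centers at radii between W/14 and W/10. The best
#' accumulator circle is returned; if its normalized score is below 0.5 the
#' result falls back to a default-radius disc flagged low-confidence.
#'
#' @param img A `fundus_image`.
#' @param center Located OD center (row, col).
#' @param cfg Configuration list.
#' @return List: `center`, `radius`, `mask` (logical), `low_confidence`,
#'   `score`.
#' @export
segment_od <- function(img, center, cfg = default_config()) {
  H <- dim(img$rgb)[1]; W <- dim(img$rgb)[2]
  g <- img$rgb[, , 2]
  lim <- 1.5 * cfg$od_window_frac * W
  r0 <- max(1, round(center[1] - lim)); r1 <- min(H, round(center[1] + lim))
  c0 <- max(1, round(center[2] - lim)); c1 <- min(W, round(center[2] + lim))
  sub <- g[r0:r1, c0:c1]
  # light denoising so edge directions are dominated by structure, not noise
  sub <- ebi_mat(EBImage::gblur(as_image(sub), sigma = 1.5))
  gr <- grad_central(sub)
  mag <- sqrt(gr$dr^2 + gr$dc^2)
  sel <- mag > stats::quantile(mag, 0.9)
  edges <- which(sel, arr.ind = TRUE)
  # unit gradient direction at each edge pixel; each pixel votes along it
  # (both senses), so a circle's rim concentrates one vote per rim pixel at
  # the center
  ur <- gr$dr[sel] / (mag[sel] + 1e-12)
  uc <- gr$dc[sel] / (mag[sel] + 1e-12)
  radii <- seq(round(W * cfg$od_radius_frac_min), round(W * cfg$od_radius_frac_max))
  nh <- nrow(sub); nw <- ncol(sub)
  box <- matrix(1, 3, 3)
  best <- list(score = -Inf, center = center, radius = round(W / 12))
  for (r in radii) {
    cr <- round(c(edges[, 1] - r * ur, edges[, 1] + r * ur))
    cc <- round(c(edges[, 2] - r * uc, edges[, 2] + r * uc))
    ok <- cr >= 1 & cr <= nh & cc >= 1 & cc <= nw
    idx <- (cc[ok] - 1L) * nh + cr[ok]
    votes <- matrix(tabulate(idx, nbins = nh * nw), nh, nw)
    # pool over a 3 x 3 neighborhood to absorb rounding spread
    pooled <- ebi_mat(EBImage::filter2(as_image(votes), box,
                                         boundary = "replicate"))
    mi <- which.max(pooled)
    score <- pooled[mi] / (2 * pi * r)
    if (score > best$score) {
      best <- list(score = min(score, 1),
                   center = c((mi - 1L) %% nh + 1L + r0 - 1L,
                              (mi - 1L) %/% nh + 1L + c0 - 1L),
                   radius = r)
    }
  }
  # a clean disc boundary concentrates roughly a third of its rim votes in
  # the pooled peak under typical noise; half of that is the confidence floor
  low_conf <- best$score < 0.15
  if (low_conf) best$center <- center
  mask <- radial_field(H, W, best$center) <= best$radius
  list(center = as.numeric(best$center), radius = best$radius, mask = mask,
       low_confidence = low_conf, score = best$score)
}
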