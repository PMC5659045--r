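#' Contrast-limited adaptive histogram equalization
#'
#' The image is divided into a grid of tiles and each tile is histogram
#' equalized with clipping; tile boundaries are bilinearly interpolated.
#'
#' @param ch A `channel_image` or numeric matrix in \[0,1\].
#' @param tiles Number of tiles per side (scalar or length-2, default 8).
#' @param clip Clip limit (default 2).
#' @return A `channel_image` with `domain = "enhanced"`.
#' @export
clahe <- function(ch, tiles = 8, clip = 2.0) {
  m <- ch_data(ch)
  tiles <- rep(as.integer(tiles), length.out = 2L)
  stopifnot(all(tiles >= 2L), clip > 0)
  if (nrow(m) < tiles[1] || ncol(m) < tiles[2])
    stop("tile grid larger than image")
  # tile grids require dims divisible by the tile counts: replicate-pad the
  # right/bottom edge to the next multiple, equalize, crop back
  H <- nrow(m); W <- ncol(m)
  H2 <- ceiling(H / tiles[1]) * tiles[1]
  W2 <- ceiling(W / tiles[2]) * tiles[2]
  mp <- m[c(seq_len(H), rep(H, H2 - H)), c(seq_len(W), rep(W, W2 - W)),
          drop = FALSE]
  # EBImage::clahe works on dim1 = x; transpose so tiles follow (row, col)
  out <- t(ebi_mat(EBImage::clahe(as_image(t(mp)), nx = tiles[2],
                                    ny = tiles[1], limit = clip)))
  channel_image(clamp01(out[seq_len(H), seq_len(W), drop = FALSE]), "enhanced")
}

#' Diffusion smoothness schedule
#'
#' Piecewise schedule for the curvature weight of the coupled correction
#' field: 40 for iterations 1--9, then decreasing by 0.7 per iteration up to
#' iteration 55, then halving each iteration from 56 on.
#'
#' @param n Iteration index (integer >= 1), vectorized.
#' @return The schedule value(s).
#' @export
a_n_value <- function(n) {
  stopifnot(all(n >= 1))
  one <- function(k) {
    if (k <= 9) return(40)
    if (k <= 55) return(40 - 0.7 * (k - 9))
    a <- 40 - 0.7 * 46          # value at 55
    a / 2^(k - 55)
  }
  vapply(as.integer(n), one, numeric(1))
}

# |grad u| * div(grad u / |grad u|): curvature motion term, regularized.
curv_term <- function(u, eps = 1e-6) {
  ux  <- (shift_mat(u, 0L, 1L) - shift_mat(u, 0L, -1L)) / 2
  uy  <- (shift_mat(u, 1L, 0L) - shift_mat(u, -1L, 0L)) / 2
  uxx <- shift_mat(u, 0L, 1L) - 2 * u + shift_mat(u, 0L, -1L)
  uyy <- shift_mat(u, 1L, 0L) - 2 * u + shift_mat(u, -1L, 0L)
  uxy <- (shift_mat(u, 1L, 1L) - shift_mat(u, 1L, -1L) -
          shift_mat(u, -1L, 1L) + shift_mat(u, -1L, -1L)) / 4
  g2 <- ux^2 + uy^2
  num <- uxx * uy^2 - 2 * ux * uy * uxy + uyy * ux^2
  num / (g2 + eps)
}

# div(grad v / |grad v|): curvature (not multiplied by |grad v|).
curvature_only <- function(v, eps = 1e-6) {
  vx  <- (shift_mat(v, 0L, 1L) - shift_mat(v, 0L, -1L)) / 2
  vy  <- (shift_mat(v, 1L, 0L) - shift_mat(v, -1L, 0L)) / 2
  vxx <- shift_mat(v, 0L, 1L) - 2 * v + shift_mat(v, 0L, -1L)
  vyy <- shift_mat(v, 1L, 0L) - 2 * v + shift_mat(v, -1L, 0L)
  vxy <- (shift_mat(v, 1L, 1L) - shift_mat(v, 1L, -1L) -
          shift_mat(v, -1L, 1L) + shift_mat(v, -1L, -1L)) / 4
  g2 <- vx^2 + vy^2
  num <- vxx * vy^2 - 2 * vx * vy * vxy + vyy * vx^2
  num / (g2 + eps)^1.5
}

#' Coupled anisotropic diffusion filtering
#'
#' Smooths the CLAHE result `M` by evolving a pair of coupled fields: the
#' filtered estimate `u` moves by edge-gated mean-curvature flow with a
#' fidelity pull toward `M`, while the correction field `v` moves by
#' curvature flow weighted by the decaying schedule [a_n_value()] and is
#' pulled toward `u` with coupling `b`. The edge gate is
#' `g(|grad v|) = 1 / (1 + l |grad v|^2)`: where `v` is smooth the flow is
#' pure curvature smoothing; across strong edges of `v` the fidelity term
#' dominates and the edge is preserved. Explicit Euler stepping, central
#' differences, both fields clamped to \[0,1\].
#'
#' @param M A `channel_image` or matrix in \[0,1\] (typically CLAHE output).
#' @param iterations Number of time steps (default 60).
#' @param b Coupling constant of the correction field (default 0.02).
#' @param l Edge-sensitivity constant (default 0.01).
#' @param dt Time step (default 0.1).
#' @param fov Optional logical mask; pixels outside it are kept frozen.
#' @return A `channel_image` with `domain = "enhanced"` (the filtered `u`).
#' @export
diffuse <- function(M, iterations = 60, b = 0.02, l = 0.01, dt = 0.1,
                    fov = NULL) {
  m0 <- ch_data(M)
  stopifnot(iterations >= 1, b > 0, l > 0)
  if (is.null(fov)) fov <- matrix(TRUE, nrow(m0), ncol(m0))
  u <- .diffuse_cpp(m0, a_n_value(seq_len(iterations)), b, l, dt, fov)
  channel_image(u, "enhanced")
}

#' Full preprocessing: green channel, CLAHE, coupled diffusion
#'
#' @param img A `fundus_image`.
#' @param cfg Configuration list (see [default_config()]).
#' @return List with `green`, `enhanced` (both `channel_image`).
#' @export
preprocess_fundus <- function(img, cfg = default_config()) {
  g <- green_channel(img)
  enh <- clahe(g, tiles = cfg$clahe_tiles, clip = cfg$clahe_clip)
  sm <- diffuse(enh, iterations = cfg$diff_iterations, b = cfg$diff_b,
                l = cfg$diff_l, dt = cfg$diff_dt, fov = img$fov)
  list(green = g, enhanced = sm)
}
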