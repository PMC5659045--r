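#' Combine two phase-congruency maps by pixel-level multiplication
#'
#' Structure present in both maps is kept, background noise appearing in only
#' one is suppressed (the product is bounded by the minimum when both maps
#' are in \[0,1\]). The product is renormalized to \[0,1\] by its maximum.
#'
#' @param pc_raw PC map of the raw green channel.
#' @param pc_enh PC map of the enhanced (CLAHE + diffusion) image.
#' @return Combined PC map in \[0,1\].
#' @export
combine_pc <- function(pc_raw, pc_enh) {
  stopifnot(all(dim(pc_raw) == dim(pc_enh)))
  prod <- pc_raw * pc_enh
  mx <- max(prod)
  if (mx == 0) {
    warning("combined PC map is identically zero")
    return(prod)
  }
  prod / mx
}

#' Isodata iterative threshold
#'
#' Fixed point of `T = (mean(values < T) + mean(values >= T)) / 2`, started
#' from the global mean, iterated until the threshold moves by less than
#' 1e-4.
#'
#' @param x Numeric matrix or vector with at least two distinct values.
#' @return The threshold (scalar).
#' @export
iterative_threshold <- function(x) {
  v <- as.numeric(x)
  v <- v[is.finite(v)]
  if (length(unique(v)) < 2L) stop("constant field has no threshold")
  t_cur <- mean(v)
  for (i in 1:200) {
    lo <- v[v < t_cur]; hi <- v[v >= t_cur]
    if (!length(lo) || !length(hi)) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < 1e-4) return(t_new)
    t_cur <- t_new
  }
  t_cur
}

#' Remove small connected components
#'
#' @param mask Logical matrix.
#' @param min_area Minimum component area in px (8-connectivity).
#' @return Filtered logical mask.
#' @export
area_filter <- function(mask, min_area) {
  stopifnot(min_area >= 1)
  if (min_area == 1 || !any(mask)) return(mask)
  labels <- label_components(mask)
  sizes <- component_sizes(labels)
  keep <- which(sizes >= min_area)
  matrix(labels %in% keep, nrow(mask), ncol(mask))
}

# Zhang-Suen thinning to a 1-px skeleton, vectorized over the image.
thin_mask <- function(mask) {
  m <- mask * 1L
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      p2 <- shift_mat(m, -1L, 0L); p3 <- shift_mat(m, -1L, 1L)
      p4 <- shift_mat(m, 0L, 1L);  p5 <- shift_mat(m, 1L, 1L)
      p6 <- shift_mat(m, 1L, 0L);  p7 <- shift_mat(m, 1L, -1L)
      p8 <- shift_mat(m, 0L, -1L); p9 <- shift_mat(m, -1L, -1L)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
           (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
           (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (phase == 1) {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- m == 1 & B >= 2 & B <= 6 & A == 1 &
          (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) { m[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1L
}

# Remove skeleton spurs shorter than `n` px by iteratively deleting endpoints.
prune_spurs <- function(skel, n = 10L) {
  m <- skel
  for (i in seq_len(n)) {
    nb <- shift_mat(m * 1L, -1L, 0L) + shift_mat(m * 1L, 1L, 0L) +
      shift_mat(m * 1L, 0L, -1L) + shift_mat(m * 1L, 0L, 1L) +
      shift_mat(m * 1L, -1L, -1L) + shift_mat(m * 1L, -1L, 1L) +
      shift_mat(m * 1L, 1L, -1L) + shift_mat(m * 1L, 1L, 1L)
    ends <- m & nb <= 1
    if (!any(ends)) break
    m[ends] <- FALSE
  }
  m
}

#' Skeleton of the main vascular arcade
#'
#' The dark main vessels are emphasized with a bottom-hat transform of the
#' green channel (disc structuring element, radius about W/40), binarized
#' with the isodata threshold, intersected with the vessel mask, thinned to
#' 1 px, short spurs pruned, and the largest connected component kept.
#'
#' @param mask Vessel `BinaryMask` (logical matrix).
#' @param green Green `channel_image` or matrix.
#' @param spur_len Spur-pruning length in px (default 10).
#' @return List: `pixels` (n x 2 matrix of (row, col)), `mask` (logical
#'   skeleton image).
#' @export
skeleton_main_arcade <- function(mask, green, spur_len = 10L) {
  if (!any(mask)) stop("no main vessels: empty vessel mask")
  g <- ch_data(green)
  radius <- max(3L, round(ncol(g) / 40))
  bh <- ebi_mat(EBImage::blackTopHat(as_image(g), disc_brush(radius)))
  thick <- bh >= iterative_threshold(bh)
  thick <- thick & mask
  if (!any(thick)) thick <- mask
  # reconnect fragments broken by the intersection before thinning
  thick <- ebi_mat(EBImage::closing(as_image(thick * 1),
                                      disc_brush(3L))) > 0.5
  skel <- prune_spurs(thin_mask(thick), spur_len)
  if (!any(skel)) stop("no main vessels: skeleton empty after pruning")
  labels <- label_components(skel)
  sizes <- component_sizes(labels)
  main <- labels == which.max(sizes)
  list(pixels = which(main, arr.ind = TRUE), mask = main)
}

#' Vessel segmentation stage
#'
#' PC maps are computed on the raw green channel and on the enhanced image,
#' combined by pixel-level multiplication, binarized with the isodata
#' threshold, and cleaned by area filtering (minimum area 30 px at a 565 px
#' image width, scaled by the squared width ratio).
#'
#' @param green Raw green `channel_image`.
#' @param enhanced Enhanced `channel_image` (CLAHE + diffusion).
#' @param cfg Configuration list.
#' @param fov Optional FOV mask; detections outside it are dropped.
#' @return List: `mask` (logical), `combined_pc`, `pc_raw`, `pc_enh`,
#'   `threshold`.
#' @export
segment_vessels <- function(green, enhanced, cfg = default_config(),
                            fov = NULL) {
  W_img <- ncol(ch_data(green))
  lam <- max(2, cfg$vessel_lambda_min * W_img / cfg$vessel_ref_width)
  pars <- pc_params(n_orient = cfg$pc_orientations, n_scale = cfg$pc_scales,
                    wavelength_min = lam, scale_factor = cfg$pc_scale_factor,
                    epsilon = cfg$pc_epsilon, noise_k = cfg$pc_noise_k,
                    sigma_onf = cfg$pc_sigma_onf)
  pc_raw <- phase_congruency(green, pars)
  pc_enh <- phase_congruency(enhanced, pars)
  comb <- combine_pc(pc_raw, pc_enh)
  if (!is.null(fov)) {
    # the aperture rim is a strong artificial edge; keep only interior PC
    inner <- erode_mat(fov, disc_brush(max(3L, round(W_img / 80))))
    comb[!inner] <- 0
  }
  thr <- iterative_threshold(comb)
  mask <- comb >= thr
  # 1 px opening: the thresholded PC response carries a thin halo around
  # the vessel core plus isolated specks
  mask <- dilate_mat(erode_mat(mask, disc_brush(1L)), disc_brush(1L))
  min_area <- max(1, round(cfg$vessel_min_area * (W_img / cfg$vessel_ref_width)^2))
  mask <- area_filter(mask, min_area)
  # vessels are tubes: drop compact blob components (lesions also produce
  # phase congruency) unless they are large enough to be arcade network
  mask <- drop_blob_components(mask, min_circ = 3,
                               big_area = round(2000 * (W_img / 565)^2))
  list(mask = mask, combined_pc = comb, pc_raw = pc_raw, pc_enh = pc_enh,
       threshold = thr)
}

# Keep components that look tubular (boundary^2 / (4 pi area) >= min_circ,
# i.e. elongated or branched) or that are large.
drop_blob_components <- function(mask, min_circ = 3, big_area = 2000) {
  labels <- label_components(mask)
  n <- max(labels)
  if (n == 0L) return(mask)
  keep <- logical(n)
  for (i in seq_len(n)) {
    comp <- labels == i
    a <- sum(comp)
    if (a >= big_area) { keep[i] <- TRUE; next }
    p <- region_perimeter(comp)
    keep[i] <- p^2 / (4 * pi * a) >= min_circ
  }
  matrix(labels %in% which(keep), nrow(mask), ncol(mask))
}
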