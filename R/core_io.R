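#' Read a color fundus photograph
#'
#' Loads an 8-bit RGB raster (PNG/TIFF/JPEG) and estimates the circular field
#' of view (FOV) as the largest connected bright region of the luminance
#' channel above a low fixed threshold (10/255), hole-filled. Grayscale input
#' is replicated to three channels with a warning.
#'
#' @param path Path to a PNG, TIFF or JPEG file.
#' @return A `fundus_image` object: list with `rgb` (H x W x 3 array in
#'   \[0,1\]), `fov` (H x W logical FOV mask), `source_id` (the file path) and
#'   `pixel_size_hint` (mm/px, `NA` if unknown).
#' @export
read_fundus <- function(path) {
  if (!file.exists(path)) stop("cannot read fundus image: ", path)
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)   # dim1 = x (col), dim2 = y (row)
  if (length(dim(dat)) == 2L) {
    warning("grayscale input converted to RGB")
    dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  }
  if (dim(dat)[3] > 3L) dat <- dat[, , 1:3, drop = FALSE]  # drop alpha
  # transpose to (row, col, channel)
  rgb <- aperm(dat[, , 1:3, drop = FALSE], c(2, 1, 3))
  fundus_image(rgb, source_id = path)
}

#' Construct a fundus image object from an RGB array
#'
#' @param rgb H x W x 3 numeric array in \[0,1\] (row, col, channel).
#' @param fov Optional logical FOV mask; estimated from luminance if missing.
#' @param source_id Free-text identifier.
#' @param pixel_size_hint Optional pixel pitch in mm/px.
#' @return A `fundus_image` object.
#' @export
fundus_image <- function(rgb, fov = NULL, source_id = "", pixel_size_hint = NA_real_) {
  stopifnot(length(dim(rgb)) == 3L, dim(rgb)[3] == 3L)
  if (dim(rgb)[1] < 64L || dim(rgb)[2] < 64L)
    stop("fundus image must be at least 64 x 64")
  rgb <- clamp01(rgb)
  if (is.null(fov)) fov <- estimate_fov(rgb)
  structure(list(rgb = rgb, fov = fov, source_id = source_id,
                 pixel_size_hint = pixel_size_hint),
            class = "fundus_image")
}

# FOV mask: luminance > 10/255, largest 8-connected component, hole fill.
estimate_fov <- function(rgb) {
  lum <- (rgb[, , 1] + rgb[, , 2] + rgb[, , 3]) / 3
  bright <- lum > 10 / 255
  if (!any(bright)) stop("no field of view found")
  labels <- label_components(bright)
  sizes <- component_sizes(labels)
  fill_holes(labels == which.max(sizes))
}

#' @export
print.fundus_image <- function(x, ...) {
  d <- dim(x$rgb)
  cat(sprintf("<fundus_image> %d x %d px, FOV %.1f%%, source '%s'\n",
              d[1], d[2], 100 * mean(x$fov), x$source_id))
  invisible(x)
}

#' Extract the green channel
#'
#' The green plane of a color fundus image carries the highest vessel/lesion
#' contrast and is the working channel of every grayscale stage.
#'
#' @param img A `fundus_image`.
#' @return A `channel_image`: list with `data` (H x W matrix in \[0,1\]) and
#'   `domain` (`"raw_green"`).
#' @export
green_channel <- function(img) {
  stopifnot(inherits(img, "fundus_image"))
  channel_image(img$rgb[, , 2], "raw_green")
}

#' Construct a channel image
#' @param data H x W numeric matrix, finite, in \[0,1\].
#' @param domain One of `"raw_green"`, `"enhanced"`, `"background"`,
#'   `"difference"`.
#' @return A `channel_image` object.
#' @export
channel_image <- function(data, domain = c("raw_green", "enhanced",
                                           "background", "difference")) {
  domain <- match.arg(domain)
  stopifnot(is.matrix(data), all(is.finite(data)))
  if (domain != "difference") stopifnot(min(data) >= 0, max(data) <= 1)
  structure(list(data = data, domain = domain), class = "channel_image")
}

ch_data <- function(x) if (inherits(x, "channel_image")) x$data else x

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP),
#' accuracy = (TP+TN)/(TP+TN+FP+FN). A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param tp,fp,tn,fn Non-negative integer counts, total at least 1.
#' @return Named list with `sensitivity`, `specificity`, `accuracy`.
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn >= 1)
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = safe_div(tp, tp + fn),
       specificity = safe_div(tn, tn + fp),
       accuracy    = safe_div(tp + tn, tp + fp + tn + fn))
}

#' Write a binary mask as a 0/255 single-channel PNG
#' @param mask H x W logical matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  stopifnot(is.matrix(mask))
  EBImage::writeImage(as_image(t(mask * 1)), path)
  invisible(path)
}

#' Read a binary mask written by [write_mask()]
#' @param path PNG path.
#' @return H x W logical matrix.
#' @export
read_mask <- function(path) {
  dat <- EBImage::imageData(EBImage::readImage(path))
  if (length(dim(dat)) == 3L) dat <- dat[, , 1]
  t(dat) > 0.5
}

#' Default pipeline configuration
#'
#' Every tunable of the pipeline as a flat named list. Values printed in the
#' source method description keep those defaults; reconstructed internals are
#' documented in the methods vignette.
#'
#' @return Named list of parameters.
#' @export
default_config <- function() {
  list(
    # preprocessing
    clahe_tiles = 8, clahe_clip = 2.0,
    diff_iterations = 60, diff_b = 0.02, diff_l = 0.01, diff_dt = 0.1,
    # phase congruency
    pc_orientations = 8, pc_scales = 3, pc_wavelength_min = 3,
    pc_scale_factor = 1.6, pc_epsilon = 1e-5, pc_noise_k = 3.0,
    pc_sigma_onf = 0.55,
    # vessels
    vessel_min_area = 30, vessel_ref_width = 565, vessel_lambda_min = 5,
    # optic disc
    od_window_frac = 1 / 6, od_radius_frac_min = 1 / 14,
    od_radius_frac_max = 1 / 10,
    # macula
    macula_levels = 4, macula_rm_frac = 1 / 20, macula_contour_levels = 5,
    macula_candidate_cap = 10,
    # microaneurysms
    ma_window = 15, ma_lambda_min = 3, ma_noise_k = 2.0,
    ma_h_min = 0.5, ma_s_max = 0.02, ma_candidate_cap = 100,
    ma_score_window = c(20, 30), ma_accept_mode = "ge", ma_accept_min = 35,
    # hemorrhages
    hem_median_kernel = 80, hem_median_ref_width = 1500, hem_kmeans_k = 5,
    hem_region_t0 = 100 / 255, hem_grow_cap_factor = 10,
    # exudates
    exu_se_frac = 1 / 30,
    # misc
    seed = 1
  )
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values are parsed
#' as numeric vectors where possible (comma-separated), else kept as strings.
#' Unknown keys error; missing keys keep their defaults.
#'
#' @param path Config file path.
#' @return Full configuration list (defaults overridden by the file).
#' @export
read_config <- function(path) {
  cfg <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) stop("cannot parse config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
    cfg[[key]] <- if (!anyNA(num)) num else val
  }
  cfg
}

#' Write a configuration list as a flat key=value file
#' @param cfg Configuration list.
#' @param path Output path.
#' @export
write_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    paste0(k, " = ", paste(cfg[[k]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

# Per-stage log line on stderr.
log_stage <- function(stage, t0, verbose = TRUE) {
  if (isTRUE(verbose))
    message(sprintf("[%s] %.2fs", stage, as.numeric(Sys.time()) - t0))
  invisible(NULL)
}
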