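#' Phase-congruency parameters
#'
#' @param n_orient Number of filter orientations (default 8).
#' @param n_scale Number of filter scales (default 3).
#' @param wavelength_min Wavelength of the smallest-scale filter in px
#'   (default 3; must be >= 2, the Nyquist limit).
#' @param scale_factor Wavelength ratio between adjacent scales (default 1.6).
#' @param epsilon Small constant guarding the denominator (default 1e-5).
#' @param noise_k Noise threshold multiplier (default 2).
#' @param sigma_onf Log-Gabor bandwidth ratio sigma/f0 (default 0.55).
#' @return A `pc_params` list.
#' @export
pc_params <- function(n_orient = 8, n_scale = 3, wavelength_min = 3,
                      scale_factor = 1.6, epsilon = 1e-5, noise_k = 2.0,
                      sigma_onf = 0.55) {
  stopifnot(n_orient >= 1, n_scale >= 1, scale_factor > 1, epsilon > 0)
  if (wavelength_min < 2) stop("wavelength_min below the 2 px Nyquist limit")
  structure(list(n_orient = n_orient, n_scale = n_scale,
                 wavelength_min = wavelength_min, scale_factor = scale_factor,
                 epsilon = epsilon, noise_k = noise_k, sigma_onf = sigma_onf),
            class = "pc_params")
}

#' Log-Gabor filter bank in the frequency domain
#'
#' Builds `n_scale * n_orient` quadrature filters: radial log-Gabor profiles
#' (Gaussian on a log-frequency axis, exactly zero at DC) centered at
#' wavelengths `wavelength_min * scale_factor^(j-1)`, times Gaussian angular
#' spreads at orientations `(i-1) * pi / n_orient`. A low-pass envelope
#' suppresses frequencies beyond 0.45 cycles/px.
#'
#' @param shape Integer pair (H, W), both >= 16.
#' @param params A [pc_params()] list.
#' @return List of lists: `filters[[scale]][[orient]]`, each an H x W matrix
#'   (unshifted frequency layout); attributes `wavelengths`, `angles`.
#' @export
loggabor_bank <- function(shape, params = pc_params()) {
  H <- shape[1]; W <- shape[2]
  stopifnot(H >= 16, W >= 16)
  # frequency coordinates in cycles/px, unshifted layout
  fy <- (seq_len(H) - 1) / H; fy[fy >= 0.5] <- fy[fy >= 0.5] - 1
  fx <- (seq_len(W) - 1) / W; fx[fx >= 0.5] <- fx[fx >= 0.5] - 1
  FY <- matrix(fy, H, W); FX <- matrix(fx, H, W, byrow = TRUE)
  radius <- sqrt(FY^2 + FX^2); radius[1, 1] <- 1   # avoid log(0); DC zeroed below
  theta <- atan2(-FY, FX)
  lowpass <- 1 / (1 + (radius / 0.45)^30)          # butterworth envelope
  wavelengths <- params$wavelength_min * params$scale_factor^(seq_len(params$n_scale) - 1)
  angles <- (seq_len(params$n_orient) - 1) * pi / params$n_orient
  sintheta <- sin(theta); costheta <- cos(theta)
  filters <- vector("list", params$n_scale)
  for (s in seq_len(params$n_scale)) {
    f0 <- 1 / wavelengths[s]
    rad <- exp(-(log(radius / f0))^2 / (2 * log(params$sigma_onf)^2)) * lowpass
    rad[1, 1] <- 0
    filters[[s]] <- vector("list", params$n_orient)
    for (o in seq_len(params$n_orient)) {
      ds <- sintheta * cos(angles[o]) - costheta * sin(angles[o])
      dc <- costheta * cos(angles[o]) + sintheta * sin(angles[o])
      dtheta <- abs(atan2(ds, dc))
      spread <- exp(-dtheta^2 / (2 * (pi / params$n_orient / 1.3)^2))
      filters[[s]][[o]] <- rad * spread
    }
  }
  structure(filters, wavelengths = wavelengths, angles = angles,
            shape = c(H, W))
}

# Mirror-pad a matrix to (H2, W2) (content in the top-left corner).
mirror_pad <- function(m, H2, W2) {
  H <- nrow(m); W <- ncol(m)
  ri <- c(seq_len(H), rev(seq_len(H)))[((seq_len(H2) - 1) %% (2 * H)) + 1]
  ci <- c(seq_len(W), rev(seq_len(W)))[((seq_len(W2) - 1) %% (2 * W)) + 1]
  m[ri, ci, drop = FALSE]
}

#' Phase congruency map
#'
#' Measures, per pixel, the degree to which the local Fourier components are
#' in phase, from the quadrature responses of a log-Gabor bank:
#' `PC = sum_o W_o * max(E_o - T_o, 0) / (sum_o sum_s A_so + epsilon)`,
#' where `E_o` is the local energy of orientation `o` accumulated over
#' scales, `T_o` a Rayleigh-based noise compensation estimated from the
#' median amplitude of the smallest-scale filter, `W_o` a sigmoid weight of
#' the filter-response spread across scales, and `A_so` the per-filter
#' amplitudes. The map is dimensionless, lies in \[0,1\], and is invariant
#' under positive affine intensity changes (filters have zero DC response and
#' the noise estimate scales with the signal).
#'
#' @param ch A `channel_image` or numeric matrix.
#' @param params A [pc_params()] list.
#' @param pad If `TRUE` (default) the image is mirror-padded to an
#'   FFT-friendly size before filtering and cropped back; `FALSE` filters at
#'   the native size (exact circular convolution).
#' @return H x W matrix in \[0,1\] (the PC map).
#' @export
phase_congruency <- function(ch, params = pc_params(), pad = TRUE) {
  img <- ch_data(ch)
  stopifnot(all(is.finite(img)))
  H <- nrow(img); W <- ncol(img)
  if (pad) {
    H2 <- good_fft_size(H + 16L); W2 <- good_fft_size(W + 16L)
  } else {
    H2 <- H; W2 <- W
  }
  work <- if (H2 > H || W2 > W) mirror_pad(img, H2, W2) else img
  bank <- loggabor_bank(c(H2, W2), params)
  IM <- stats::fft(work)
  npx <- H2 * W2
  num <- matrix(0, H2, W2)
  den <- matrix(0, H2, W2)
  for (o in seq_len(params$n_orient)) {
    sumE <- matrix(0, H2, W2); sumO <- matrix(0, H2, W2)
    sumAn <- matrix(0, H2, W2); maxAn <- matrix(0, H2, W2)
    es <- vector("list", params$n_scale); os <- vector("list", params$n_scale)
    tau <- NA_real_
    for (s in seq_len(params$n_scale)) {
      resp <- stats::fft(IM * bank[[s]][[o]], inverse = TRUE) / npx
      e <- Re(resp); od <- Im(resp)
      An <- sqrt(e^2 + od^2)
      es[[s]] <- e; os[[s]] <- od
      sumE <- sumE + e; sumO <- sumO + od
      sumAn <- sumAn + An; maxAn <- pmax(maxAn, An)
      if (s == 1L) tau <- stats::median(An) / sqrt(log(4))
    }
    XE <- sqrt(sumE^2 + sumO^2) + params$epsilon
    MeanE <- sumE / XE; MeanO <- sumO / XE
    E_o <- matrix(0, H2, W2)
    for (s in seq_len(params$n_scale))
      E_o <- E_o + es[[s]] * MeanE + os[[s]] * MeanO -
        abs(es[[s]] * MeanO - os[[s]] * MeanE)
    # Rayleigh noise model: total amplitude over scales of a flat-spectrum
    # noise, mean + noise_k standard deviations
    m <- 1 / params$scale_factor
    total_tau <- tau * (1 - m^params$n_scale) / (1 - m)
    noise_mean <- total_tau * sqrt(pi / 2)
    noise_sd <- total_tau * sqrt((4 - pi) / 2)
    T_o <- noise_mean + params$noise_k * noise_sd
    width <- (sumAn / (maxAn + params$epsilon)) / params$n_scale
    W_o <- 1 / (1 + exp(10 * (0.5 - width)))
    num <- num + W_o * pmax(E_o - T_o, 0)
    den <- den + sumAn
  }
  pc <- num / (den + params$epsilon)
  pc <- pmin(pmax(pc[seq_len(H), seq_len(W), drop = FALSE], 0), 1)
  pc
}
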