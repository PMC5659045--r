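# Shared fixtures, all generated in code.

.phantom_cache <- new.env(parent = emptyenv())

# Memoised phantom generation (several test files reuse the same seeds).
cached_phantom <- function(seed, ...) {
  key <- paste0("s", seed, "_", paste(unlist(list(...)), collapse = "_"))
  if (is.null(.phantom_cache[[key]]))
    .phantom_cache[[key]] <- generate_phantom(phantom_spec(seed = seed, ...))
  .phantom_cache[[key]]
}

dice_coef <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Radially symmetric Gaussian dot (bright) on a flat field.
gauss_dot_image <- function(H, W, center, sigma, amp = 0.5, base = 0.2) {
  r <- matrix(seq_len(H), H, W) - center[1]
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  base + amp * exp(-(r^2 + c^2) / (2 * sigma^2))
}

# Vertical ridge (bright line along rows) of the given width.
ridge_image <- function(H, W, col0, width, amp = 0.5, base = 0.2) {
  c <- matrix(seq_len(W), H, W, byrow = TRUE)
  base + amp * exp(-(c - col0)^2 / (2 * (width / 2)^2))
}

# Plain-R morphological reconstruction oracle (pixel loops, 8-connectivity).
reconstruct_oracle <- function(marker, mask) {
  cur <- pmin(marker, mask)
  H <- nrow(cur); W <- ncol(cur)
  repeat {
    changed <- FALSE
    for (i in seq_len(H)) for (j in seq_len(W)) {
      nb <- cur[max(1, i - 1):min(H, i + 1), max(1, j - 1):min(W, j + 1)]
      v <- min(max(nb), mask[i, j])
      if (v > cur[i, j] + 1e-12) { cur[i, j] <- v; changed <- TRUE }
    }
    if (!changed) return(cur)
  }
}

# Direct circular-convolution evaluation of a frequency-domain filter.
spatial_filter_oracle <- function(img, filt) {
  H <- nrow(img); W <- ncol(img)
  kern <- stats::fft(filt, inverse = TRUE) / (H * W)
  out <- matrix(complex(real = 0), H, W)
  for (p in seq_len(H)) for (q in seq_len(W)) {
    ip <- ((p - seq_len(H)) %% H) + 1
    iq <- ((q - seq_len(W)) %% W) + 1
    out[p, q] <- sum(img * kern[ip, iq])
  }
  out
}
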