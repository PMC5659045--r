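# Internal helpers shared across the pipeline. All grayscale processing uses
# plain numeric matrices in (row, col) orientation, values in [0, 1].

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# Shift a matrix by (dr, dc) with replicated (clamped-index) borders.
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Central differences with replicated borders.
grad_central <- function(m) {
  list(
    dr = (shift_mat(m, 1L, 0L) - shift_mat(m, -1L, 0L)) / 2,
    dc = (shift_mat(m, 0L, 1L) - shift_mat(m, 0L, -1L)) / 2
  )
}

# Disc-shaped logical brush of the given radius (EBImage convention).
disc_brush <- function(radius) {
  size <- 2L * as.integer(radius) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# Matrix -> EBImage::Image and back; EBImage stores dim1 = x (columns of the
# display), but a plain matrix passes through morphological ops unchanged in
# layout, so only symmetric brushes are used on transposed data.
as_image <- function(m) EBImage::Image(m)

# Image -> plain base matrix (as.matrix on an Image keeps the S4 class).
ebi_mat <- function(img) {
  d <- EBImage::imageData(img)
  if (length(dim(d)) > 2L) d <- d[, , 1]
  d
}

dilate_mat <- function(m, brush) {
  ebi_mat(EBImage::dilate(as_image(m * 1), brush)) > 0.5
}

erode_mat <- function(m, brush) {
  ebi_mat(EBImage::erode(as_image(m * 1), brush)) > 0.5
}

# Grayscale dilation/erosion on numeric matrices.
gdilate_mat <- function(m, brush) ebi_mat(EBImage::dilate(as_image(m), brush))
gerode_mat  <- function(m, brush) ebi_mat(EBImage::erode(as_image(m), brush))

# Connected-component labelling with 8-connectivity. EBImage::bwlabel is
# 4-connected; labels touching diagonally are merged with a union-find over
# the label graph.
label_components <- function(mask) {
  lab <- ebi_mat(EBImage::bwlabel(as_image(mask * 1)))
  n <- max(lab)
  if (n <= 1L) return(lab)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  H <- nrow(lab); W <- ncol(lab)
  for (sh in list(c(1L, 1L), c(1L, -1L))) {
    a <- lab[seq_len(H - 1L), , drop = FALSE]
    b <- lab[seq_len(H - 1L) + 1L, , drop = FALSE]
    if (sh[2] == 1L) { a <- a[, seq_len(W - 1L), drop = FALSE]; b <- b[, seq_len(W - 1L) + 1L, drop = FALSE] }
    else             { a <- a[, seq_len(W - 1L) + 1L, drop = FALSE]; b <- b[, seq_len(W - 1L), drop = FALSE] }
    touch <- a > 0L & b > 0L & a != b
    if (any(touch)) {
      prs <- unique(cbind(a[touch], b[touch]))
      for (k in seq_len(nrow(prs))) {
        ra <- find(prs[k, 1]); rb <- find(prs[k, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  compact <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0L] <- compact[lab[lab > 0L]]
  out
}

component_sizes <- function(labels) {
  tab <- tabulate(labels[labels > 0L])
  tab
}

fill_holes <- function(mask) {
  ebi_mat(EBImage::fillHull(as_image(mask * 1))) > 0.5
}

# Centroid (row, col) of a logical mask.
mask_centroid <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  c(mean(idx[, 1]), mean(idx[, 2]))
}

# Euclidean distance field from the image centre of shape (H, W).
radial_field <- function(H, W, center = c((H + 1) / 2, (W + 1) / 2)) {
  r <- matrix(seq_len(H), H, W) - center[1]
  c <- matrix(seq_len(W), H, W, byrow = TRUE) - center[2]
  sqrt(r^2 + c^2)
}

# Next FFT-friendly size (2^a * 3^b * 5^c) >= n, for fast mixed-radix FFTs.
good_fft_size <- function(n) {
  m <- n
  repeat {
    k <- m
    for (p in c(2L, 3L, 5L)) while (k %% p == 0L) k <- k %/% p
    if (k == 1L) return(m)
    m <- m + 1L
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
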