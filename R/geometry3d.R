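# Equivalent optical eye model: spherical-cap geometry from camera and eye
# measurements, and back-projection of planar detections onto the cap.

#' Derive the spherical-cap eye geometry
#'
#' From the camera working distance `AB` (mm), the axial length `BD` (mm),
#' the fundus-image height `EF` (mm) and the field angle `alpha` (degrees):
#' `EC = EF/2`, `CD = AB + BD - EC * cot(alpha/2)`, `ED = sqrt(EC^2 + CD^2)`,
#' `beta = atan(EC/CD)`, `R = ED / (2 cos(beta))`. The imaged fundus is the
#' cap of the sphere of radius `R` between the rim chord `EF` and the pole
#' `D`; the rim-to-axis angle at the sphere center is
#' `beta_cap = 180 - 2 beta` degrees.
#'
#' @param AB Working distance in mm (> 0).
#' @param BD Axial length in mm (> 0).
#' @param EF Fundus-image height in mm (> 0).
#' @param alpha Field angle in degrees, in (0, 180).
#' @param center Sphere-axis position `(g, h)` in image-plane mm
#'   (default c(0, 0)).
#' @param theta Cap half-angle bound in degrees (default 90).
#' @return An `eye_geometry` list with all input and derived quantities
#'   (`EC`, `CD`, `ED`, `beta`, `R`, `beta_cap`, `g`, `h`, `theta`).
#' @export
derive_geometry <- function(AB, BD, EF, alpha, center = c(0, 0), theta = 90) {
  stopifnot(AB > 0, BD > 0, alpha > 0, alpha < 180)
  if (EF <= 0) stop("degenerate image: EF must be positive")
  EC <- EF / 2
  CD <- AB + BD - EC / tan(alpha * pi / 360)
  if (CD <= 0) stop("inconsistent camera geometry: CD <= 0")
  ED <- sqrt(EC^2 + CD^2)
  beta <- atan(EC / CD)                     # radians
  R <- ED / (2 * cos(beta))
  beta_cap <- pi - 2 * beta
  structure(list(AB = AB, BD = BD, EF = EF, alpha = alpha,
                 EC = EC, CD = CD, ED = ED,
                 beta = beta * 180 / pi, R = R,
                 beta_cap = beta_cap * 180 / pi,
                 g = center[1], h = center[2], theta = theta),
            class = "eye_geometry")
}

#' Back-project a pixel onto the spherical cap
#'
#' The pixel's radial fraction `r` in \[0,1\] from the field-of-view center
#' maps linearly to the polar angle `phi = r * beta_cap` on the cap
#' (equal-angular mapping); the azimuth is preserved. The returned point
#' satisfies `(x-g)^2 + (y-h)^2 + z^2 = R^2` by construction, with the cap
#' pole (image center) at `z = -R`.
#'
#' @param pixel (row, col), inside the FOV.
#' @param img_shape (H, W) of the source image.
#' @param geom An `eye_geometry`.
#' @param fov_center Optional FOV center (row, col); defaults to the image
#'   center.
#' @param fov_radius_px Optional FOV radius in px; defaults to the inscribed
#'   circle radius.
#' @return Named numeric vector `(x, y, z)` in mm; attributes
#'   `source_pixel`.
#' @export
project_to_sphere <- function(pixel, img_shape, geom, fov_center = NULL,
                              fov_radius_px = NULL) {
  H <- img_shape[1]; W <- img_shape[2]
  if (is.null(fov_center)) fov_center <- c((H + 1) / 2, (W + 1) / 2)
  if (is.null(fov_radius_px)) fov_radius_px <- min(H, W) / 2
  dr <- pixel[1] - fov_center[1]; dc <- pixel[2] - fov_center[2]
  rfrac <- sqrt(dr^2 + dc^2) / fov_radius_px
  if (rfrac > 1 + 1e-9) stop("pixel outside field of view")
  phi <- rfrac * geom$beta_cap * pi / 180
  psi <- atan2(-dr, dc)       # x to the right, y upward
  R <- geom$R
  out <- c(x = geom$g + R * sin(phi) * cos(psi),
           y = geom$h + R * sin(phi) * sin(psi),
           z = -R * cos(phi))
  attr(out, "source_pixel") <- pixel
  out
}

#' Invert the spherical back-projection
#'
#' @param point Named or plain numeric (x, y, z) on the cap.
#' @param img_shape (H, W).
#' @param geom An `eye_geometry`.
#' @param fov_center,fov_radius_px As in [project_to_sphere()].
#' @return The source (row, col).
#' @export
unproject_from_sphere <- function(point, img_shape, geom, fov_center = NULL,
                                  fov_radius_px = NULL) {
  H <- img_shape[1]; W <- img_shape[2]
  if (is.null(fov_center)) fov_center <- c((H + 1) / 2, (W + 1) / 2)
  if (is.null(fov_radius_px)) fov_radius_px <- min(H, W) / 2
  R <- geom$R
  phi <- acos(pmin(pmax(-point[3] / R, -1), 1))
  psi <- atan2(point[2] - geom$h, point[1] - geom$g)
  rfrac <- phi / (geom$beta_cap * pi / 180)
  rpx <- rfrac * fov_radius_px
  c(fov_center[1] - rpx * sin(psi), fov_center[2] + rpx * cos(psi))
}

#' Tessellate the imaged cap into a colored triangle mesh
#'
#' A regular pixel grid (given stride) inside the FOV is projected onto the
#' cap; grid cells whose four corners are all inside the FOV become two
#' triangles each, so every interior edge is shared by exactly two faces.
#' Vertex colors are the image RGB overlaid with class colors: vessels red,
#' hemorrhages blue, exudates yellow, microaneurysms magenta, marked
#' centers white.
#'
#' @param img A `fundus_image`.
#' @param masks Named list of logical overlay masks (any of `vessels`,
#'   `hemorrhage`, `exudate`, `ma`, `centers`).
#' @param geom An `eye_geometry`.
#' @param stride Grid stride in px (default 4).
#' @return List: `vertices` (n x 3), `colors` (n x 3 in 0..255), `faces`
#'   (m x 3, 1-based vertex indices), `source_pixels` (n x 2).
#' @export
build_mesh <- function(img, masks = list(), geom, stride = 4L) {
  H <- dim(img$rgb)[1]; W <- dim(img$rgb)[2]
  fc <- mask_centroid(img$fov)
  frad <- sqrt(sum(img$fov) / pi)
  rows <- seq(1L, H, by = stride); cols <- seq(1L, W, by = stride)
  grid_id <- matrix(0L, length(rows), length(cols))
  verts <- list(); cols_rgb <- list(); pix <- list()
  overlay <- list(vessels = c(255, 0, 0), hemorrhage = c(0, 0, 255),
                  exudate = c(255, 255, 0), ma = c(255, 0, 255),
                  centers = c(255, 255, 255))
  nid <- 0L
  for (i in seq_along(rows)) for (j in seq_along(cols)) {
    r <- rows[i]; cl <- cols[j]
    d <- sqrt((r - fc[1])^2 + (cl - fc[2])^2)
    if (d > frad || !img$fov[r, cl]) next
    nid <- nid + 1L
    grid_id[i, j] <- nid
    verts[[nid]] <- project_to_sphere(c(r, cl), c(H, W), geom,
                                      fov_center = fc, fov_radius_px = frad)
    col <- round(255 * c(img$rgb[r, cl, 1], img$rgb[r, cl, 2],
                         img$rgb[r, cl, 3]))
    for (nm in names(masks))
      if (!is.null(overlay[[nm]]) && isTRUE(masks[[nm]][r, cl]))
        col <- overlay[[nm]]
    cols_rgb[[nid]] <- col
    pix[[nid]] <- c(r, cl)
  }
  faces <- list()
  for (i in seq_len(length(rows) - 1L)) for (j in seq_len(length(cols) - 1L)) {
    a <- grid_id[i, j]; b <- grid_id[i, j + 1L]
    cc <- grid_id[i + 1L, j]; dd <- grid_id[i + 1L, j + 1L]
    if (a > 0L && b > 0L && cc > 0L && dd > 0L) {
      faces[[length(faces) + 1L]] <- c(a, b, dd)
      faces[[length(faces) + 1L]] <- c(a, dd, cc)
    }
  }
  list(vertices = do.call(rbind, verts),
       colors = do.call(rbind, cols_rgb),
       faces = if (length(faces)) do.call(rbind, faces)
               else matrix(integer(0), 0, 3),
       source_pixels = do.call(rbind, pix))
}

#' Write a colored triangle mesh as ASCII PLY
#'
#' @param mesh Mesh list from [build_mesh()].
#' @param path Output `.ply` path.
#' @export
write_ply <- function(mesh, path) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nv),
               "property float x", "property float y", "property float z",
               "property uchar red", "property uchar green",
               "property uchar blue",
               paste("element face", nf),
               "property list uchar int vertex_indices",
               "end_header"), con)
  vl <- sprintf("%.6f %.6f %.6f %d %d %d",
                mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3],
                mesh$colors[, 1], mesh$colors[, 2], mesh$colors[, 3])
  writeLines(vl, con)
  if (nf)
    writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                       mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}
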