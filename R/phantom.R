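# Synthetic fundus phantom with exact ground truth.

#' Phantom specification
#'
#' Describes a synthetic fundus image: circular field of view, a parabolic
#' dark vascular arcade with branch vessels, a bright circular optic disc
#' near the arcade vertex, a dark inverse-Gaussian macula, and planted
#' lesions (dark microaneurysm dots of 1-3 px radius, dark hemorrhage blobs
#' of 4-12 px radius, bright sharp-edged exudate patches of 4-16 px radius).
#' Red lesions are 15-40 percent darker than their surroundings in the green
#' channel, exudates 20-50 percent brighter; two soft-edged bright
#' illumination artifacts are included as realistic distractors. Additive
#' Gaussian noise and a radial vignette complete the image.
#'
#' @param shape (H, W), default c(584, 565).
#' @param seed RNG seed; generation is deterministic given the spec.
#' @param n_ma,n_hem,n_exu,n_artifact Object counts (defaults 10, 5, 5, 2).
#' @param noise_sigma Additive noise SD (default 0.03).
#' @param vignette Peak relative darkening at the FOV rim (default 0.08).
#' @param od_side `"left"`, `"right"` or `"random"`.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(584, 565), seed = 1, n_ma = 10, n_hem = 5,
                         n_exu = 5, n_artifact = 2, noise_sigma = 0.03,
                         vignette = 0.08, od_side = "random") {
  structure(list(shape = shape, seed = seed, n_ma = n_ma, n_hem = n_hem,
                 n_exu = n_exu, n_artifact = n_artifact,
                 noise_sigma = noise_sigma, vignette = vignette,
                 od_side = od_side),
            class = "phantom_spec")
}

# Distance field to a set of curve points (rasterized, then distance
# transform); returns distances in px.
curve_distance <- function(H, W, pts) {
  raster <- matrix(TRUE, H, W)  # TRUE = background for distmap
  rr <- round(pts[, 1]); cc <- round(pts[, 2])
  ok <- rr >= 1 & rr <= H & cc >= 1 & cc <= W
  raster[cbind(rr[ok], cc[ok])] <- FALSE
  ebi_mat(EBImage::distmap(as_image(raster * 1)))
}

#' Generate a synthetic fundus phantom
#'
#' @param spec A [phantom_spec()].
#' @return List: `image` (a `fundus_image`) and `truth` (list of per-class
#'   logical masks `vessels`, `od`, `macula`, `ma`, `hemorrhage`, `exudate`;
#'   `od_center`, `od_radius`, `macula_center`, `arcade_vertex`; centroid
#'   matrices `ma_centers`, `hem_centers`, `exu_centers`; `counts`;
#'   `grade` from [grade_npdr()] on the true counts).
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  set.seed(spec$seed)
  H <- spec$shape[1]; W <- spec$shape[2]
  sc <- W / 565                       # resolution scale factor
  ctr <- c(H / 2, W / 2)
  fovr <- 0.48 * min(H, W)
  dctr <- radial_field(H, W, ctr)
  fov <- dctr <= fovr

  g <- matrix(0.45, H, W)
  # gentle illumination gradient
  g <- g + 0.03 * (matrix(seq_len(W), H, W, byrow = TRUE) - W / 2) / W

  side <- spec$od_side
  if (side == "random") side <- sample(c("left", "right"), 1)
  od_r <- 45 * sc
  vx_r <- ctr[1] + stats::runif(1, -0.05, 0.05) * H
  vx_c <- if (side == "left") 0.27 * W else 0.73 * W
  open_sign <- if (side == "left") 1 else -1
  # arcade: col = vx_c + open_sign * a * (row - vx_r)^2
  a_coef <- stats::runif(1, 0.0016, 0.0024) / sc
  od_center <- c(vx_r + stats::runif(1, -10, 10) * sc,
                 vx_c + stats::runif(1, -10, 10) * sc)

  # optic disc: bright, soft 2 px edge
  d_od <- radial_field(H, W, od_center)
  g <- g + 0.25 / (1 + exp((d_od - od_r) / 1.5))
  od_mask <- d_od <= od_r

  # macula: inverse-Gaussian dark region, about 2.5 OD radii clear of the OD
  mac_center <- c(vx_r + stats::runif(1, -8, 8) * sc,
                  vx_c + open_sign * stats::runif(1, 2.6, 3.0) * 2 * od_r)
  mac_sigma <- W / 25
  d_mac <- radial_field(H, W, mac_center)
  mac_depth <- 0.18
  g <- g - mac_depth * exp(-d_mac^2 / (2 * mac_sigma^2))
  mac_mask <- d_mac <= mac_sigma

  # vessels: main arcade parabola plus branches radiating from the OD
  rows_arc <- seq(max(1, vx_r - 0.42 * H), min(H, vx_r + 0.42 * H), by = 0.5)
  arc_pts <- cbind(rows_arc, vx_c + open_sign * a_coef * (rows_arc - vx_r)^2)
  widths <- c(6, 4, 4, 3, 3) * sc
  curves <- list(arc_pts)
  for (b in 1:4) {
    ang <- stats::runif(1, 0, 2 * pi)
    len <- stats::runif(1, 0.25, 0.45) * W
    tt <- seq(0, len, by = 0.5)
    bend <- stats::runif(1, -0.002, 0.002)
    curves[[b + 1]] <- cbind(od_center[1] + tt * sin(ang) + bend * tt^2,
                             od_center[2] + tt * cos(ang) + bend * tt^2 / 2)
  }
  vessel_mask <- matrix(FALSE, H, W)
  contrast_v <- 0.22
  for (i in seq_along(curves)) {
    dv <- curve_distance(H, W, curves[[i]])
    w2 <- widths[i] / 2
    g <- g - contrast_v * exp(-dv^2 / (2 * (w2 / 1.2)^2))
    vessel_mask <- vessel_mask | (dv <= w2)
  }
  vessel_mask <- vessel_mask & fov

  place <- function(n, rmin, rmax, avoid_dist) {
    out <- matrix(numeric(0), 0, 3)
    attempts <- 0
    while (nrow(out) < n) {
      attempts <- attempts + 1
      if (attempts > 1000 * n) stop("infeasible lesion placement")
      r <- stats::runif(1, rmin, rmax)
      rc <- ctr + stats::runif(2, -1, 1) * (fovr - r - 20 * sc)
      if (sqrt(sum((rc - ctr)^2)) > fovr - r - 15 * sc) next
      if (sqrt(sum((rc - od_center)^2)) < 1.4 * od_r + r) next
      if (sqrt(sum((rc - mac_center)^2)) < W / 40 + r) next
      rr <- round(rc[1]); cc <- round(rc[2])
      if (rr < 1 || rr > H || cc < 1 || cc > W) next
      win <- vessel_mask[max(1, rr - round(avoid_dist)):min(H, rr + round(avoid_dist)),
                         max(1, cc - round(avoid_dist)):min(W, cc + round(avoid_dist))]
      if (any(win)) next
      if (nrow(out) &&
          any(sqrt((out[, 1] - rc[1])^2 + (out[, 2] - rc[2])^2) <
              out[, 3] + r + 12 * sc)) next
      out <- rbind(out, c(rc, r))
    }
    out
  }

  ma_mask <- matrix(FALSE, H, W)
  mas <- if (spec$n_ma > 0) place(spec$n_ma, 1.5 * sc, 3 * sc, 8 * sc)
         else matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(mas))) {
    d <- radial_field(H, W, mas[i, 1:2])
    contrast <- stats::runif(1, 0.15, 0.40) * 0.45
    g <- g - contrast * exp(-d^2 / (2 * (mas[i, 3] / 1.1)^2))
    ma_mask <- ma_mask | (d <= mas[i, 3])
  }

  hem_mask <- matrix(FALSE, H, W)
  hems <- if (spec$n_hem > 0) place(spec$n_hem, 4 * sc, 12 * sc, 14 * sc)
          else matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(hems))) {
    contrast <- stats::runif(1, 0.15, 0.40) * 0.45
    blob <- matrix(FALSE, H, W)
    nsub <- sample(2:4, 1)
    for (k in seq_len(nsub)) {
      off <- stats::runif(2, -0.5, 0.5) * hems[i, 3]
      rsub <- stats::runif(1, 0.55, 0.9) * hems[i, 3]
      blob <- blob | (radial_field(H, W, hems[i, 1:2] + off) <= rsub)
    }
    db <- ebi_mat(EBImage::distmap(as_image((!blob) * 1)))  # dist to blob
    depth <- contrast * pmax(1 - db / 1.5, 0)      # sharp 1.5 px shoulder
    g <- g - depth
    hem_mask <- hem_mask | blob
  }

  exu_mask <- matrix(FALSE, H, W)
  exus <- if (spec$n_exu > 0) place(spec$n_exu, 4 * sc, 16 * sc, 10 * sc)
          else matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(exus))) {
    contrast <- stats::runif(1, 0.20, 0.50) * 0.45
    blob <- matrix(FALSE, H, W)
    nsub <- sample(2:3, 1)
    for (k in seq_len(nsub)) {
      off <- stats::runif(2, -0.4, 0.4) * exus[i, 3]
      rsub <- stats::runif(1, 0.6, 0.95) * exus[i, 3]
      blob <- blob | (radial_field(H, W, exus[i, 1:2] + off) <= rsub)
    }
    db <- ebi_mat(EBImage::distmap(as_image((!blob) * 1)))  # dist to blob
    g <- g + contrast * pmax(1 - db / 1.0, 0)      # sharp 1 px shoulder
    exu_mask <- exu_mask | blob
  }

  # soft-edged bright illumination artifacts (not exudates)
  arts <- if (spec$n_artifact > 0) place(spec$n_artifact, 10 * sc, 16 * sc, 10 * sc)
          else matrix(numeric(0), 0, 3)
  for (i in seq_len(nrow(arts))) {
    d <- radial_field(H, W, arts[i, 1:2])
    g <- g + 0.10 * exp(-d^2 / (2 * (2.5 * arts[i, 3])^2))
  }

  # vignette, noise, FOV aperture
  g <- g * (1 - spec$vignette * (dctr / fovr)^2)
  g <- g + matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
  g <- clamp01(g)
  g[!fov] <- 0

  red <- clamp01(0.30 + 0.9 * g + matrix(stats::rnorm(H * W, 0, spec$noise_sigma / 2), H, W))
  blue <- clamp01(0.35 * g + matrix(stats::rnorm(H * W, 0, spec$noise_sigma / 2), H, W))
  red[!fov] <- 0; blue[!fov] <- 0
  rgb <- array(c(red, g, blue), dim = c(H, W, 3))
  img <- fundus_image(rgb, fov = fov, source_id = sprintf("phantom-seed%d", spec$seed))

  counts <- c(n_ma = nrow(mas), n_hem = nrow(hems), n_exu = nrow(exus))
  qh <- quadrant_counts(hems[, 1:2, drop = FALSE], mac_center)
  truth <- list(vessels = vessel_mask, od = od_mask, macula = mac_mask,
                ma = ma_mask & fov, hemorrhage = hem_mask & fov,
                exudate = exu_mask & fov,
                od_center = od_center, od_radius = od_r,
                macula_center = mac_center,
                arcade_vertex = c(vx_r, vx_c),
                ma_centers = mas[, 1:2, drop = FALSE],
                hem_centers = hems[, 1:2, drop = FALSE],
                exu_centers = exus[, 1:2, drop = FALSE],
                artifacts = arts,
                counts = counts,
                grade = grade_npdr(counts[1], counts[2], counts[3], qh))
  list(image = img, truth = truth)
}

#' Build labeled training tables from phantoms
#'
#' Runs the pre-classifier candidate extraction on a series of phantoms and
#' labels every candidate by ground-truth overlap: at least 50 percent
#' overlap with a planted lesion gives the positive class of that type;
#' otherwise the negative subclass is `"vessel"` when the candidate overlaps
#' the true vessel mask, else `"background"` (hemorrhage table) /
#' `"artifact"` (exudate table). Vessel removal is skipped during extraction
#' so that vessel fragments appear among the negatives, mirroring the class
#' structure a clinical training set provides.
#'
#' @param n_images Number of phantoms (>= 1).
#' @param seed Base seed; phantom i uses `seed + i`.
#' @param shape Phantom shape.
#' @param cfg Configuration list.
#' @param ... Further arguments to [phantom_spec()] (lesion counts etc.).
#' @return List of two data frames, `hemorrhage` (label + 6 features) and
#'   `exudate` (label + 6 features).
#' @export
make_training_table <- function(n_images = 12, seed = 100,
                                shape = c(584, 565), cfg = default_config(),
                                ...) {
  stopifnot(n_images >= 1)
  set.seed(seed)
  hrows <- list(); erows <- list()
  for (i in seq_len(n_images)) {
    ph <- generate_phantom(phantom_spec(shape = shape, seed = seed + i, ...))
    img <- ph$image; tr <- ph$truth
    g <- green_channel(img)
    enh <- clahe(g, cfg$clahe_tiles, cfg$clahe_clip)
    enh <- diffuse(enh, iterations = cfg$diff_iterations, b = cfg$diff_b,
                   l = cfg$diff_l, dt = cfg$diff_dt, fov = img$fov)
    # hemorrhage candidates WITHOUT vessel removal
    D <- hemorrhage_background(enh, cfg)
    km <- kmeans_segment(D, K = cfg$hem_kmeans_k, mask = img$fov)
    cand <- dark_cluster_mask(km, D, mask = img$fov)
    cand <- cand & erode_mat(img$fov, disc_brush(max(3L, round(ncol(g$data) / 60))))
    cand <- area_filter(cand, max(4, round(10 * (ncol(g$data) / 565)^2)))
    labels <- label_components(cand)
    for (j in seq_len(max(labels))) {
      idx <- which(labels == j, arr.ind = TRUE)
      seedpx <- idx[which.min(g$data[idx]), ]
      bb <- c(range(idx[, 1]), range(idx[, 2]))
      hh <- bb[2] - bb[1] + 1; ww <- bb[4] - bb[3] + 1
      win <- c(max(1, bb[1] - hh), min(nrow(g$data), bb[2] + hh),
               max(1, bb[3] - ww), min(ncol(g$data), bb[4] + ww))
      cap_i <- max(50, cfg$hem_grow_cap_factor * nrow(idx))
      reg <- region_grow(g$data, seedpx, T0 = cfg$hem_region_t0, window = win,
                         cap = cap_i)
      if (nrow(reg) >= cap_i || isTRUE(attr(reg, "degenerate"))) reg <- idx
      if (nrow(reg) < 4) next
      fv <- extract_features(reg, g$data)
      if (anyNA(fv)) next
      ov_h <- mean(tr$hemorrhage[reg]); ov_v <- mean(tr$vessels[reg])
      ov_m <- mean(tr$ma[reg])
      lab <- if (ov_h >= 0.5 || ov_m >= 0.5) "hemorrhage"
             else if (ov_v >= 0.5) "vessel" else "background"
      hrows[[length(hrows) + 1]] <- c(list(label = lab), as.list(fv))
    }
    # background negatives: regions grown from random lesion-free seeds;
    # the clean phantom background yields few spontaneous dark candidates,
    # while clinical difference images are full of them
    inner_fov <- erode_mat(img$fov, disc_brush(20L))
    forbid <- tr$hemorrhage | tr$ma | tr$exudate |
      dilate_mat(tr$vessels, disc_brush(3L)) | tr$od | tr$macula
    pool <- which(inner_fov & !forbid)
    n_bg <- 0L
    for (pix in sample(pool, min(200L, length(pool)))) {
      if (n_bg >= 8L) break
      sd_pt <- c((pix - 1L) %% nrow(g$data) + 1L,
                 (pix - 1L) %/% nrow(g$data) + 1L)
      win <- c(max(1, sd_pt[1] - 15), min(nrow(g$data), sd_pt[1] + 15),
               max(1, sd_pt[2] - 15), min(ncol(g$data), sd_pt[2] + 15))
      reg <- region_grow(g$data, sd_pt, T0 = cfg$hem_region_t0,
                         window = win, cap = 120)
      if (nrow(reg) < 4) next
      fv <- extract_features(reg, g$data)
      if (anyNA(fv)) next
      hrows[[length(hrows) + 1]] <- c(list(label = "background"), as.list(fv))
      n_bg <- n_bg + 1L
    }
    # exudate candidates (no OD removal; the OD itself is an artifact here)
    bm <- background_morph(g$data, max(3L, round(ncol(g$data) * cfg$exu_se_frac)))
    edges <- kirsch_edges(ebi_mat(EBImage::gblur(as_image(g$data), sigma = 1.5)))
    pars <- pc_params(n_orient = cfg$pc_orientations, n_scale = cfg$pc_scales,
                      wavelength_min = max(2, cfg$vessel_lambda_min *
                                             ncol(g$data) / cfg$vessel_ref_width),
                      scale_factor = cfg$pc_scale_factor,
                      epsilon = cfg$pc_epsilon, noise_k = cfg$pc_noise_k,
                      sigma_onf = cfg$pc_sigma_onf)
    pcmap <- phase_congruency(g$data, pars)
    ec <- exudate_candidates(bm$bright, edges, od = NULL, fov = img$fov,
                             green = g$data, pc = pcmap)
    for (cd in ec) {
      ov <- mean(tr$exudate[cd$pixels])
      lab <- if (ov >= 0.5) "exudate" else "artifact"
      erows[[length(erows) + 1]] <- c(list(label = lab), as.list(cd$features))
    }
    # soft bright artifacts rarely pass candidate extraction (that is the
    # point of the edge gate); add their regions explicitly as negatives
    for (k in seq_len(nrow(tr$artifacts))) {
      actr <- tr$artifacts[k, 1:2]; ar <- tr$artifacts[k, 3]
      d <- radial_field(nrow(g$data), ncol(g$data), actr)
      amask <- d <= ar
      idx <- which(amask, arr.ind = TRUE)
      if (nrow(idx) < 4) next
      ring <- dilate_mat(amask, disc_brush(2L)) & !amask
      bnd <- amask & !erode_mat(amask, disc_brush(1L))
      fv <- extract_features(idx, g$data)
      feats <- c(circularity = unname(fv["circularity"]),
                 eccentricity = unname(fv["eccentricity"]),
                 m_in = mean(g$data[amask]),
                 m_d = mean(g$data[ring]) - mean(g$data[amask]),
                 pc_boundary = mean(pcmap[bnd]),
                 edge_strength = max(edges[bnd]))
      erows[[length(erows) + 1]] <- c(list(label = "artifact"), as.list(feats))
    }
  }
  hem <- do.call(rbind, lapply(hrows, as.data.frame))
  exu <- do.call(rbind, lapply(erows, as.data.frame))
  for (tab in list(hem, exu)) {
    if (is.null(tab) || length(unique(tab$label)) < 2)
      stop("training table missing a class; generate more phantoms")
  }
  list(hemorrhage = hem, exudate = exu)
}
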