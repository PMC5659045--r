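test_that("wavelet candidates find a single dark spot", {
  img <- 1 - gauss_dot_image(160, 160, c(80, 90), sigma = 8, amp = 0.3,
                             base = 0.3)
  cand <- qsdwt_candidates(img, levels = 3)
  expect_lt(sqrt(sum((cand[1, 1:2] - c(80, 90))^2)), 2.5)
  expect_error(qsdwt_candidates(matrix(0.5, 64, 64), levels = 3),
               "no candidates")
})

test_that("minima inside the optic-disc exclusion zone are dropped", {
  img <- 1 - gauss_dot_image(160, 160, c(80, 110), sigma = 8, amp = 0.25,
                             base = 0.3)
  # a darker shadow right next to the OD
  img <- img - 0.35 * exp(-((row(img) - 80)^2 + (col(img) - 42)^2) / (2 * 4^2))
  od <- list(center = c(80, 40), radius = 12)
  cand <- qsdwt_candidates(img, levels = 3, od = od)
  d_shadow <- sqrt((cand[, 1] - 80)^2 + (cand[, 2] - 42)^2)
  expect_true(all(d_shadow > 6))
  expect_lt(min(sqrt((cand[, 1] - 80)^2 + (cand[, 2] - 110)^2)), 3)
})

test_that("contour score prefers symmetric smooth depressions", {
  H <- 120; W <- 120
  sym <- 1 - gauss_dot_image(H, W, c(60, 60), sigma = 8, amp = 0.3, base = 0.3)
  s_sym <- contour_score(sym, c(60, 60), r_m = 20)
  # elongated blob of equal depth
  r <- row(matrix(0, H, W)); c <- col(matrix(0, H, W))
  elong <- 0.7 - 0.3 * exp(-((r - 60)^2 / (2 * 16^2) + (c - 60)^2 / (2 * 3^2)))
  s_el <- contour_score(elong, c(60, 60), r_m = 20)
  expect_gt(s_sym, s_el)
  # ragged sharp-edged blob scores below the smooth one
  set.seed(51)
  blob <- matrix(0.7, H, W)
  ang <- atan2(r - 60, c - 60); rad <- sqrt((r - 60)^2 + (c - 60)^2)
  blob[rad <= 8 + 3 * sin(5 * ang)] <- 0.4
  s_rag <- contour_score(blob, c(60, 60), r_m = 20)
  expect_gt(s_sym, s_rag)
  # constant window: zero
  expect_equal(contour_score(matrix(0.5, 80, 80), c(40, 40), r_m = 15), 0)
})

test_that("macula localization hits the phantom fovea", {
  for (sd in c(11, 12)) {
    ph <- cached_phantom(sd)
    g <- green_channel(ph$image)
    od <- list(center = ph$truth$od_center, radius = ph$truth$od_radius)
    res <- locate_macula_stage(g, od = od, fov = ph$image$fov)
    expect_lt(sqrt(sum((res$center - ph$truth$macula_center)^2)),
              ncol(g$data) / 40)
  }
})

test_that("localization is independent of the optic-disc position", {
  H <- 300; W <- 300
  mk <- function(od_col) {
    img <- 1 - gauss_dot_image(H, W, c(150, 210), sigma = 15, amp = 0.25,
                               base = 0.45)
    d <- sqrt((row(matrix(0, H, W)) - 150)^2 +
              (col(matrix(0, H, W)) - od_col)^2)
    img + 0.3 * exp(-pmax(d - 20, 0)^2 / 8) * (d <= 24)
  }
  od1 <- list(center = c(150, 60), radius = 22)
  od2 <- list(center = c(150, 110), radius = 22)
  r1 <- locate_macula_stage(mk(60), od = od1)
  r2 <- locate_macula_stage(mk(110), od = od2)
  expect_lt(sqrt(sum((r1$center - r2$center)^2)), 3)
})

test_that("gain and offset changes preserve the chosen candidate", {
  ph <- cached_phantom(11)
  g <- ph$image$rgb[, , 2]
  od <- list(center = ph$truth$od_center, radius = ph$truth$od_radius)
  r1 <- locate_macula_stage(g, od = od, fov = ph$image$fov)
  r2 <- locate_macula_stage(0.6 * g + 0.2, od = od, fov = ph$image$fov)
  expect_equal(r1$center, r2$center)
})

test_that("a single candidate is returned unconditionally", {
  img <- matrix(0.5, 80, 80)
  cand <- matrix(c(40, 40, 0.2), 1, 3,
                 dimnames = list(NULL, c("row", "col", "value")))
  res <- locate_macula(img, cand, r_m = 10)
  expect_equal(res$center, c(40, 40))
})
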