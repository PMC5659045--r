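test_that("parabola fitting recovers exact and noisy coefficients", {
  k <- 0:4
  pts <- cbind(2 * k^2 + 3 * k + 1, k)     # rows = f(k), cols = k
  fit <- fit_parabola(pts, "y_of_x")
  expect_equal(c(fit$a0, fit$a1, fit$a2), c(2, 3, 1), tolerance = 1e-9)
  expect_equal(fit$residual, 0, tolerance = 1e-12)
  expect_equal(fit$vertex[2], -3 / 4, tolerance = 1e-9)

  # collinear points: no curvature, vertex undefined
  lin <- cbind(2 * (0:9) + 1, 0:9)
  flin <- fit_parabola(lin, "y_of_x")
  expect_equal(flin$a0, 0, tolerance = 1e-9)
  expect_true(all(is.na(flin$vertex)))

  # noisy quadratic: matches the closed-form normal-equations oracle
  set.seed(41)
  kk <- runif(200, -2, 2)
  ll <- kk^2 + rnorm(200, 0, 0.1)
  fitn <- fit_parabola(cbind(ll, kk), "y_of_x")
  X <- cbind(kk^2, kk, 1)
  oracle <- solve(crossprod(X), crossprod(X, ll))
  expect_equal(fitn$a0, oracle[1], tolerance = 1e-9)
  expect_equal(fitn$a0, 1.00, tolerance = 0.02)
  expect_error(fit_parabola(cbind(rep(1, 5), rep(2, 5)), "y_of_x"),
               "degenerate")
})

test_that("arcade orientation is chosen by residual", {
  r <- seq(20, 180, by = 1)
  left_open <- cbind(r, 30 + 0.01 * (r - 100)^2)   # col = f(row): x_of_y
  fit <- choose_arcade_fit(left_open, c(200, 200))
  expect_equal(fit$orientation, "x_of_y")
  expect_equal(fit$vertex, c(100, 30), tolerance = 1)
  down_u <- cbind(30 + 0.01 * (r - 100)^2, r)      # row = f(col): y_of_x
  fit2 <- choose_arcade_fit(down_u, c(200, 200))
  expect_equal(fit2$orientation, "y_of_x")
  straight <- cbind(r, rep(50, length(r)))
  expect_error(choose_arcade_fit(straight, c(200, 200)), "degenerate")
})

test_that("window response rewards bright variegated discs", {
  H <- 120; W <- 120
  rgb <- array(0.3, dim = c(H, W, 3))
  img <- fundus_image(rgb + 0.2)        # uniform: variance zero
  expect_equal(window_response(img, c(60, 60), 30), 0)
  expect_error(window_response(img, c(5, 5), 30), "outside")

  # OD-like patch: bright disc with dark crossings vs flat background
  rgb2 <- array(0.35, dim = c(H, W, 3))
  d <- sqrt(outer((1:H) - 40, rep(1, W))^2 + outer(rep(1, H), (1:W) - 40)^2)
  for (ch in 1:3) {
    pl <- rgb2[, , ch]
    pl[d <= 14] <- 0.8
    pl[38:42, 20:60] <- 0.2            # vessel band through the disc
    rgb2[, , ch] <- pl
  }
  img2 <- fundus_image(rgb2)
  r_od <- window_response(img2, c(40, 40), 30)
  r_bg <- window_response(img2, c(85, 85), 30)
  expect_gt(r_od, r_bg)
})

test_that("doubling the intensity variance doubles the response", {
  H <- 80; W <- 80
  set.seed(43)
  noise <- matrix(rnorm(H * W, 0, 0.04), H, W)
  mk <- function(n) {
    # reddish base so the mean A factor is stable and positive
    rgb <- array(0, dim = c(H, W, 3))
    rgb[, , 1] <- 0.75; rgb[, , 2] <- 0.45; rgb[, , 3] <- 0.3
    rgb[, , 2] <- pmin(pmax(rgb[, , 2] + n, 0), 1)
    fundus_image(rgb)
  }
  i1 <- mk(noise); i2 <- mk(noise * sqrt(2))
  # the A factor changes only marginally; compare variance-normalized
  v1 <- stats::var(as.numeric(retinascreen:::hsi_i_channel(i1)))
  v2 <- stats::var(as.numeric(retinascreen:::hsi_i_channel(i2)))
  r1 <- window_response(i1, c(40, 40), 30)
  r2 <- window_response(i2, c(40, 40), 30)
  expect_equal(r2 / r1, v2 / v1, tolerance = 0.1)
  expect_equal(r2 / r1, 2, tolerance = 0.25)
})

test_that("Hough segmentation recovers a clean disc and falls back gracefully", {
  H <- 240; W <- 280                    # radius sweep: W/14..W/10 = 20..28
  rgb <- array(0.3, dim = c(H, W, 3))
  d <- sqrt(outer((1:H) - 120, rep(1, W))^2 + outer(rep(1, H), (1:W) - 150)^2)
  for (ch in 1:3) rgb[, , ch][d <= 24] <- 0.75
  img <- fundus_image(rgb, fov = matrix(TRUE, H, W))
  seg <- segment_od(img, c(120, 150))
  expect_false(seg$low_confidence)
  expect_equal(seg$radius, 24, tolerance = 2)
  expect_lte(sqrt(sum((seg$center - c(120, 150))^2)), 2.5)

  # quarter-occluded disc: center still close
  rgb2 <- rgb
  for (ch in 1:3) rgb2[, , ch][112:128, ] <- 0.2
  img2 <- fundus_image(rgb2, fov = matrix(TRUE, H, W))
  seg2 <- segment_od(img2, c(120, 150))
  expect_lt(sqrt(sum((seg2$center - c(120, 150))^2)), 3)

  # featureless image: low-confidence fallback at the prior center
  img3 <- fundus_image(array(0.4, dim = c(H, W, 3)) +
                         array(runif(H * W * 3, 0, 0.01), dim = c(H, W, 3)),
                       fov = matrix(TRUE, H, W))
  seg3 <- segment_od(img3, c(120, 150))
  expect_true(seg3$low_confidence)
  expect_equal(seg3$center, c(120, 150))
})

test_that("locating from a clipped vertex still returns an in-image point", {
  ph <- cached_phantom(11)
  fake_par <- structure(list(a0 = 1, a1 = 0, a2 = 0, orientation = "y_of_x",
                             vertex = c(1, 1), residual = 0),
                        class = "parabola")
  loc <- locate_od(ph$image, fake_par)
  expect_true(loc$center[1] >= 1 && loc$center[2] >= 1)
  expect_true(loc$center[1] <= 584 && loc$center[2] <= 565)
})
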