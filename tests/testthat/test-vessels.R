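test_that("pixel-level multiplication suppresses one-sided responses", {
  line <- matrix(0, 32, 32); line[, 16] <- 1
  expect_equal(combine_pc(line, line), line)
  noise <- line; noise[5, 5] <- 0.8          # blob present in one map only
  comb <- combine_pc(line, noise)
  expect_lte(comb[5, 5], min(line[5, 5], noise[5, 5]))
  expect_warning(z <- combine_pc(matrix(0, 4, 4), matrix(0, 4, 4)), "zero")
  expect_true(all(z == 0))
})

test_that("isodata threshold solves its fixed-point equation", {
  x <- c(rep(0, 50), rep(1, 50))
  expect_equal(iterative_threshold(x), 0.5)
  # brute-force scan for the fixed point on a small asymmetric sample
  v <- c(0, 0, 0, 0.9, 1.0, 1.1) / 1.1
  t_pkg <- iterative_threshold(v)
  fixed <- vapply(seq(0.01, 0.99, by = 0.001), function(t) {
    lo <- v[v < t]; hi <- v[v >= t]
    if (!length(lo) || !length(hi)) return(Inf)
    abs((mean(lo) + mean(hi)) / 2 - t)
  }, numeric(1))
  t_scan <- seq(0.01, 0.99, by = 0.001)[which.min(fixed)]
  expect_lt(abs(t_pkg - t_scan), 0.005)
  expect_gt(t_pkg, max(v[v < 0.5]))
  expect_lt(t_pkg, min(v[v > 0.5]))
  expect_error(iterative_threshold(rep(0.3, 10)), "constant")
})

test_that("isodata threshold splits a balanced Gaussian mixture at the midpoint", {
  set.seed(31)
  x <- c(rnorm(5000, 0.2, 0.02), rnorm(5000, 0.8, 0.02))
  expect_lt(abs(iterative_threshold(x) - 0.5), 0.02)
})

test_that("thresholding its own binarization is idempotent", {
  set.seed(32)
  x <- c(rnorm(500, 0.3, 0.05), rnorm(500, 0.7, 0.05))
  t1 <- iterative_threshold(x)
  t2 <- iterative_threshold((x >= t1) * 1)
  expect_equal(t2, iterative_threshold((x >= t2) * 1))
})

test_that("area filtering removes exactly the small components", {
  m <- matrix(FALSE, 40, 40)
  m[2:6, 2] <- TRUE                      # 5 px
  m[20:29, 10:14] <- TRUE                # 50 px
  out <- area_filter(m, 30)
  expect_false(any(out[2:6, 2]))
  expect_true(all(out[20:29, 10:14]))
  expect_identical(area_filter(m, 1), m)
  # planted specks are removed, the main structure kept
  set.seed(33)
  big <- matrix(FALSE, 100, 100); big[40:60, 10:90] <- TRUE
  specks <- big
  for (k in 1:20) {
    p <- c(sample(c(1:30, 70:100), 1), sample(1:98, 1))
    specks[p[1], p[2] + 0:2] <- TRUE
  }
  filt <- area_filter(specks, 10)
  lab <- retinascreen:::label_components(filt)
  expect_equal(max(lab), 1)
})

test_that("skeleton of a parabolic band follows the analytic curve", {
  H <- 200; W <- 200
  g <- matrix(0.6, H, W)
  mask <- matrix(FALSE, H, W)
  for (r in 1:H) {
    c0 <- 40 + 0.004 * (r - 100)^2
    for (d in -3:3) {
      cc <- round(c0 + d)
      if (cc >= 1 && cc <= W) { mask[r, cc] <- TRUE; g[r, cc] <- 0.3 }
    }
  }
  sk <- skeleton_main_arcade(mask, g, spur_len = 5L)
  expect_gt(nrow(sk$pixels), 50)
  # every skeleton point close to the analytic parabola
  d <- abs(sk$pixels[, 2] - (40 + 0.004 * (sk$pixels[, 1] - 100)^2))
  expect_lt(stats::quantile(d, 0.95), 2)
  # a short disjoint arc is discarded in favor of the long one
  mask2 <- mask; mask2[5:15, 150] <- TRUE
  g2 <- g; g2[5:15, 150] <- 0.3
  sk2 <- skeleton_main_arcade(mask2, g2, spur_len = 5L)
  expect_false(any(sk2$pixels[, 2] == 150 & sk2$pixels[, 1] <= 15))
  expect_error(skeleton_main_arcade(matrix(FALSE, 10, 10), matrix(0.5, 10, 10)),
               "empty")
})

test_that("phantom vessel masks overlap ground truth across seeds", {
  dices <- vapply(1:5, function(sd) {
    ph <- cached_phantom(sd)
    pp <- preprocess_fundus(ph$image)
    ves <- segment_vessels(pp$green, pp$enhanced, fov = ph$image$fov)
    dice_coef(ves$mask, ph$truth$vessels)
  }, numeric(1))
  expect_true(all(dices >= 0.75))
})
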