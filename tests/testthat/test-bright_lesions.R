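test_that("opening-by-reconstruction isolates small bright blobs", {
  const <- matrix(0.4, 32, 32)
  bm <- background_morph(const, se_radius = 4)
  expect_true(all(bm$bright == 0))
  # small bright blob on a smooth ramp
  ramp <- matrix(seq(0.2, 0.4, length.out = 32), 32, 32, byrow = TRUE)
  img <- ramp
  d <- retinascreen:::radial_field(32, 32, c(16, 16))
  img[d <= 3] <- img[d <= 3] + 0.3
  bm2 <- background_morph(img, se_radius = 6)
  expect_gt(min(bm2$bright[d <= 1.5]), 0.2)
  # ramp restored away from the blob (the last columns have no brighter
  # neighbor to propagate from, an intrinsic border effect)
  off_blob <- d > 6 & col(img) <= 24
  expect_lt(max(bm2$bright[off_blob]), 0.01)
  # reconstruction properties and oracle agreement
  expect_true(all(bm2$background <= img + 1e-9))
  expect_true(all(bm2$bright >= 0))
  marker <- retinascreen:::gerode_mat(img, retinascreen:::disc_brush(6))
  oracle <- reconstruct_oracle(marker, img)
  expect_lt(max(abs(bm2$background - oracle)), 1e-6)
})

test_that("a blob wider than the structuring element survives in the background", {
  img <- matrix(0.3, 48, 48)
  d <- retinascreen:::radial_field(48, 48, c(24, 24))
  img[d <= 15] <- 0.6
  bm <- background_morph(img, se_radius = 5)
  expect_lt(max(bm$bright), 0.05)     # levelled into the background
})

test_that("Kirsch edges respond as hand-computed on steps and rotations", {
  expect_true(all(abs(kirsch_edges(matrix(0.5, 20, 20))) < 1e-9))
  h <- 0.4
  step <- matrix(0, 20, 20); step[, 11:20] <- h
  resp <- kirsch_edges(step)
  # template weights {5,-3}: a 3-px column of height h against the zero side
  expect_equal(max(resp[5:15, ]), 15 * h, tolerance = 1e-6)
  # 90-degree rotation permutes templates but preserves the field
  set.seed(71)
  rot90 <- function(m) t(m[nrow(m):1, , drop = FALSE])
  img <- matrix(runif(400), 20, 20)
  r_rot <- kirsch_edges(rot90(img))
  expect_lt(max(abs(r_rot - rot90(kirsch_edges(img)))), 1e-9)
})

test_that("exudate candidates are bright, sharp, and exclude the optic disc", {
  ph <- cached_phantom(11)
  g <- ph$image$rgb[, , 2]
  bm <- background_morph(g)
  gs <- retinascreen:::ebi_mat(EBImage::gblur(EBImage::Image(g), sigma = 1.5))
  edges <- kirsch_edges(gs)
  od <- list(mask = ph$truth$od, radius = ph$truth$od_radius)
  cands <- exudate_candidates(bm$bright, edges, od = od, fov = ph$image$fov,
                              green = g)
  expect_gt(length(cands), 0)
  for (cd in cands) expect_false(any(ph$truth$od[cd$pixels]))
  # most planted exudates appear among the candidates
  hits <- vapply(seq_len(nrow(ph$truth$exu_centers)), function(k) {
    any(vapply(cands, function(cd)
      sqrt(sum((cd$centroid - ph$truth$exu_centers[k, ])^2)) < 20,
      logical(1)))
  }, logical(1))
  expect_gte(sum(hits), nrow(ph$truth$exu_centers) - 1)
})

test_that("the exudate SVM accepts sharp patches and rejects soft ones", {
  set.seed(72)
  n <- 40
  mk <- function(label, circ, ecc, min_, md, pcb) {
    data.frame(label = label,
               circularity = circ + rnorm(n, 0, 0.2),
               eccentricity = ecc + rnorm(n, 0, 0.05),
               m_in = min_ + rnorm(n, 0, 0.02),
               m_d = md + rnorm(n, 0, 0.02),
               pc_boundary = pcb + rnorm(n, 0, 0.03))
  }
  tab <- rbind(mk("exudate", 1.5, 0.5, 0.7, -0.25, 0.4),
               mk("artifact", 2.5, 0.7, 0.55, -0.05, 0.05))
  mod <- train_exudate_svm(tab, seed = 1)
  expect_gt(mod$cv_accuracy, 0.9)
  cands <- list(list(features = c(circularity = 1.4, eccentricity = 0.5,
                                  m_in = 0.7, m_d = -0.25, pc_boundary = 0.45)),
                list(features = c(circularity = 2.6, eccentricity = 0.72,
                                  m_in = 0.54, m_d = -0.04, pc_boundary = 0.03)))
  keep <- classify_exudates(cands, mod)
  expect_true(keep[1])
  expect_false(keep[2])
  expect_identical(classify_exudates(list(), mod), logical(0))
  expect_error(classify_exudates(cands, "nope"), "untrained")
})
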