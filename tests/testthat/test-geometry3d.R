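test_that("the geometry chain matches direct evaluation of its formulas", {
  geom <- derive_geometry(AB = 20, BD = 20, EF = 20, alpha = 90)
  # independent oracle: direct evaluation
  EC <- 20 / 2
  CD <- 40 - EC / tan(pi / 4)
  ED <- sqrt(EC^2 + CD^2)
  beta <- atan(EC / CD)
  R <- ED / (2 * cos(beta))
  expect_equal(geom$EC, 10)
  expect_equal(geom$CD, 30)
  expect_equal(geom$ED, ED)
  expect_equal(geom$ED, sqrt(1000), tolerance = 1e-12)
  expect_equal(geom$beta, beta * 180 / pi)
  expect_equal(geom$beta, 18.43495, tolerance = 1e-4)
  expect_equal(geom$R, R)
  expect_equal(geom$R, 16.66667, tolerance = 1e-4)
})

test_that("geometry limits and errors behave", {
  g <- derive_geometry(AB = 20, BD = 20, EF = 20, alpha = 179.999)
  expect_equal(g$CD, 40, tolerance = 1e-3)     # cot(alpha/2) -> 0
  expect_error(derive_geometry(20, 20, 0, 90), "degenerate")
  expect_error(derive_geometry(1, 1, 50, 20), "inconsistent")
})

test_that("the derived radius is scale-equivariant", {
  g1 <- derive_geometry(25, 24, 18, 45)
  for (c in c(0.5, 2, 3.7)) {
    g2 <- derive_geometry(25 * c, 24 * c, 18 * c, 45)
    expect_equal(g2$R, c * g1$R, tolerance = 1e-12)
  }
})

test_that("back-projection lands on the sphere and inverts to the pixel", {
  geom <- derive_geometry(25, 24, 18, 45)
  shape <- c(200, 200)
  # the image center maps to the cap pole
  pole <- project_to_sphere(c(100.5, 100.5), shape, geom)
  expect_equal(unname(pole["z"]), -geom$R, tolerance = 1e-9)
  # a rim pixel sits at the cap boundary angle
  rim <- project_to_sphere(c(100.5, 200), shape, geom,
                           fov_center = c(100.5, 100.5), fov_radius_px = 99.5)
  phi <- acos(-rim["z"] / geom$R) * 180 / pi
  expect_equal(unname(phi), geom$beta_cap, tolerance = 1e-6)
  # every projected pixel satisfies the sphere equation; round trip < 0.5 px
  set.seed(91)
  for (i in 1:25) {
    px <- c(runif(1, 30, 170), runif(1, 30, 170))
    pt <- project_to_sphere(px, shape, geom)
    resid <- abs((pt["x"] - geom$g)^2 + (pt["y"] - geom$h)^2 + pt["z"]^2 -
                   geom$R^2)
    expect_lt(unname(resid), 1e-6 * geom$R^2)
    back <- unproject_from_sphere(pt, shape, geom)
    expect_lt(sqrt(sum((back - px)^2)), 0.5)
  }
  expect_error(project_to_sphere(c(1, 1), shape, geom), "outside")
})

test_that("the cap mesh is watertight and carries class colors", {
  ph <- cached_phantom(11)
  geom <- derive_geometry(25, 24, 18, 45)
  mesh <- build_mesh(ph$image,
                     masks = list(hemorrhage = ph$truth$hemorrhage,
                                  exudate = ph$truth$exudate),
                     geom = geom, stride = 8L)
  expect_gt(nrow(mesh$vertices), 100)
  # all vertices satisfy the sphere equation
  res <- abs((mesh$vertices[, 1] - geom$g)^2 + (mesh$vertices[, 2] - geom$h)^2 +
               mesh$vertices[, 3]^2 - geom$R^2)
  expect_lt(max(res), 1e-6 * geom$R^2)
  # interior edges shared by exactly two faces
  edges <- rbind(mesh$faces[, 1:2], mesh$faces[, 2:3], mesh$faces[, c(3, 1)])
  key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
  expect_true(all(table(key) <= 2))
  # hemorrhage vertices colored blue
  hem_v <- which(vapply(seq_len(nrow(mesh$source_pixels)), function(i)
    ph$truth$hemorrhage[mesh$source_pixels[i, 1], mesh$source_pixels[i, 2]],
    logical(1)))
  if (length(hem_v))
    expect_true(all(mesh$colors[hem_v, 3] == 255 & mesh$colors[hem_v, 1] == 0))
  # PLY export is well-formed ASCII
  path <- tempfile(fileext = ".ply")
  write_ply(mesh, path)
  lines <- readLines(path)
  expect_equal(lines[1], "ply")
  expect_equal(sum(lines == "end_header"), 1)
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", lines,
                                                   value = TRUE)))
  expect_equal(nv, nrow(mesh$vertices))
  unlink(path)
})
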