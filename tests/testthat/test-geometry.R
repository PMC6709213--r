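test_that("disparity matches the printed extremes and the vergence formula", {
  # on-axis nearest row: printed extreme
  expect_equal(disparityOfPoint(0, 1.5), -48.4, tolerance = 0.05 / 48.4)
  # fixation plane: exactly zero
  expect_identical(disparityOfPoint(0, 0), 0)
  # on-axis farthest row, frozen from 2*(atan(0.4/10) - atan(0.4/11.5))
  expect_equal(disparityOfPoint(0, -1.5), 35.822, tolerance = 1e-4)
  # near = crossed = negative on axis
  expect_lt(disparityOfPoint(0, 0.9), 0)
  expect_gt(disparityOfPoint(0, -0.9), 0)
})

test_that("disparity is strictly decreasing in z at fixed x", {
  for (x in c(0, 0.7, -1.3)) {
    d <- disparityOfPoint(x, seq(-2, 2, by = 0.1))
    expect_true(all(diff(d) < 0))
  }
})

test_that("off-axis disparity behaves as the viewing geometry predicts", {
  xs <- seq(0, 1.8, by = 0.2)
  # near rows: |disparity| maximal on axis
  for (z in c(0.3, 0.9, 1.5)) {
    d <- abs(disparityOfPoint(xs, z))
    expect_equal(which.max(d), 1L)
  }
  # far rows: peripheral points appear further away (disparity grows with |x|)
  for (z in c(-0.3, -0.9, -1.5)) {
    d <- disparityOfPoint(xs, z)
    expect_true(all(diff(d) > 0))
  }
})

test_that("points at or behind the eyes are rejected", {
  expect_error(disparityOfPoint(0, 10), "behind the eyes")
  expect_error(disparityOfPoint(0, 11), "behind the eyes")
  expect_error(sceneToEcc(1, 10.5), "behind the eyes")
})

test_that("eccentricity conversion is symmetric and matches atan", {
  expect_identical(sceneToEcc(0, 1), 0)
  expect_equal(sceneToEcc(1.9864, -1.5), 9.8, tolerance = 0.05 / 9.8)
  xs <- runif(20, -2, 2)
  expect_equal(sceneToEcc(xs, 0.5), sceneToEcc(-xs, 0.5))
})

test_that("sphere radius interpolates the rendered anchors", {
  expect_equal(sphereRadiusAt(-1.5), 0.73)
  expect_equal(sphereRadiusAt(1.5), 0.55)
  expect_equal(sphereRadiusAt(0), 0.64)
  expect_warning(sphereRadiusAt(2.5), "extrapolating")
})

test_that("the grid has 36 staggered locations inside the printed ranges", {
  g <- makeGrid()
  loc <- gridLocations(g)
  expect_identical(nrow(loc), 36L)
  expect_identical(sort(unique(loc$z_scene)),
    c(-1.5, -0.9, -0.3, 0.3, 0.9, 1.5))
  expect_identical(length(unique(loc$col_index)), 6L)
  expect_equal(range(loc$ecc_deg), c(0.9, 9.8), tolerance = 1e-9)
  # staggered: adjacent rows use different x sets
  x1 <- sort(loc$x_scene[loc$row_index == 1])
  x2 <- sort(loc$x_scene[loc$row_index == 2])
  expect_false(any(x1 %in% x2))
})

test_that("a grid and its mirror sample 72 distinct locations", {
  g <- makeGrid()
  gm <- makeGrid(mirrored = TRUE)
  expect_identical(gridLocations(g)$z_scene, gridLocations(gm)$z_scene)
  expect_identical(gridLocations(gm)$x_scene, -gridLocations(g)$x_scene)
  u <- unique(rbind(
    gridLocations(g)[c("x_scene", "z_scene")],
    gridLocations(gm)[c("x_scene", "z_scene")]))
  expect_identical(nrow(u), 72L)
  # deterministic construction
  expect_identical(gridLocations(makeGrid()), gridLocations(g))
})

test_that("the constructed grid reproduces the published row-average disparities", {
  loc <- gridLocations(makeGrid())
  avg <- tapply(loc$disparity_arcmin, loc$z_scene, mean)
  pub <- depthRowDisparities()
  expect_lt(max(abs(as.vector(avg[as.character(pub$z_scene)]) -
    pub$disparity_arcmin)), 0.3)
})

test_that("spacing that exceeds the displayable field is rejected", {
  sp <- gridSpacing(eccRange = c(0.9, 20))
  expect_error(makeGrid(spacing = sp), "outside the displayable")
})

test_that("grid CSV round trip preserves the locations", {
  g <- makeGrid()
  path <- withr::local_tempfile(fileext = ".csv")
  exportGrid(g, path)
  g2 <- importGrid(path)
  expect_equal(gridLocations(g2), gridLocations(g), tolerance = 1e-12)
})

test_that("viewer geometry invariants are enforced", {
  expect_error(ViewerGeometry(eyeOffset = -1), "eyeOffset")
  expect_error(ViewerGeometry(fixationDistance = 0.2), "fixationDistance")
  expect_error(ViewerGeometry(horizontalFov = 190), "0, 180")
})
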