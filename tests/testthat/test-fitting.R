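test_that("the fitted curve family evaluates exactly", {
  px <- pixelCoords(PixelGrid())
  expect_equal(curveEval(px, 0, 3, 0, 1.7), rep(1.7, 111))   # a = 0
  expect_equal(curveEval(0.5, 0.5, 3, 2, 0.1), 2.1)          # peak = b + a
  expect_equal(curveEval(1.5, 0, 3, 1, 0.2), 0.2 + 1 / 128)  # half size
  expect_equal(curveEval(5, 0, 3, 1, 0.2), 0.2)              # outside support
})

test_that("grid fit recovers on-grid parameters and handles flat curves", {
  px <- PixelGrid()
  # 0.55 and 3.0 are nodes of the (-2.75 + k 0.1) x (1.5 + k 0.1) grid
  y <- curveEval(pixelCoords(px), 0.55, 3.0, 1, 0)
  f <- gridFit(y, px)
  expect_equal(unname(fitParams(f)), c(0.55, 3.0, 1, 0), tolerance = 1e-8)
  expect_lt(fitRmse(f), 1e-10)
  flat <- gridFit(rep(2, 111), px)
  expect_identical(flat@amplitude, 0)
  expect_equal(flat@baseline, 2)
  expect_error(gridFit(c(rep(1, 110), NA), px), "finite")
})

test_that("off-grid centers land on an adjacent grid node and refine to the
           truth", {
  px <- PixelGrid()
  pre <- precomputeFitGrid(px)
  y <- curveEval(pixelCoords(px), 0.5, 3.0, 1, 0)
  g <- gridFit(y, px, pre = pre)
  expect_true(isTRUE(all.equal(g@center, 0.45)) ||
    isTRUE(all.equal(g@center, 0.55)))
  f <- fitRepresentation(y, px, pre = pre)
  expect_lt(abs(f@center - 0.5), 0.01)
  expect_identical(f@stage, "refined")
})

test_that("refinement never increases the RMSE and stays within bounds", {
  px <- PixelGrid()
  pre <- precomputeFitGrid(px)
  set.seed(41)
  for (i in 1:25) {
    y <- curveEval(pixelCoords(px), runif(1, -2.5, 2.5), runif(1, 1.6, 12),
      runif(1, 0.5, 2), runif(1, -1, 1)) + rnorm(111, sd = 0.05)
    f <- fitRepresentation(y, px, pre = pre)
    expect_lte(f@rmse, f@gridRmse + 1e-12)
    expect_gte(f@amplitude, 0)
    expect_lte(f@amplitude, max(y) - min(y) + 1e-12)
    expect_gte(f@baseline, -5)
    expect_lte(f@baseline, 5)
  }
})

test_that("adding a constant shifts only the baseline", {
  px <- PixelGrid()
  pre <- precomputeFitGrid(px)
  y <- curveEval(pixelCoords(px), -0.8, 4.2, 1.3, 0.2)
  f0 <- fitRepresentation(y, px, pre = pre)
  f1 <- fitRepresentation(y + 1.5, px, pre = pre)
  expect_equal(f1@center, f0@center, tolerance = 1e-4)
  expect_equal(f1@size, f0@size, tolerance = 1e-3)
  expect_equal(f1@amplitude, f0@amplitude, tolerance = 1e-3)
  expect_equal(f1@baseline, f0@baseline + 1.5, tolerance = 1e-3)
})

test_that("parameter recovery under noise meets the accuracy target", {
  px <- PixelGrid()
  pre <- precomputeFitGrid(px)
  set.seed(42)
  errs <- vapply(1:40, function(i) {
    cTrue <- runif(1, -2.5, 2.5)
    a <- runif(1, 0.5, 2)
    y <- curveEval(pixelCoords(px), cTrue, runif(1, 1.6, 12), a,
      runif(1, -1, 1)) + rnorm(111, sd = 0.05 * a)
    abs(fitRepresentation(y, px, pre = pre)@center - cTrue)
  }, 0)
  expect_lt(median(errs), 0.1)
})

test_that("fitReconstruction tabulates fits with center errors", {
  sim <- noiselessExperiment("z", nRuns = 2, nVoxels = 15, seed = 43)
  avg <- averageByPosition(
    crossvalReconstruct(subjectData(sim, 1), buildBasis(), axis = "z"))
  tab <- fitReconstruction(avg)
  expect_identical(nrow(tab), 6L)
  expect_true(all(c("center", "rmse", "stage", "center_error") %in% names(tab)))
  expect_true(all(tab$center_error < 0.15))
})

test_that("center error is the absolute deviation", {
  expect_identical(centerError(0.3, -0.3), 0.6)
  expect_identical(centerError(-0.3, 0.3), 0.6)
  expect_identical(centerError(1.2, 1.2), 0)
  f <- new("CurveFit", center = 0.4, size = 2, amplitude = 1, baseline = 0,
    rmse = 0, gridRmse = 0, stage = "grid")
  expect_equal(centerError(f, 0.1), 0.3)
})
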