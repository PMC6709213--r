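test_that("voxel populations are reproducible and respect the weight law", {
  v1 <- makeVoxels(50, seed = 3)
  v2 <- makeVoxels(50, seed = 3)
  expect_identical(v1@weights, v2@weights)
  expect_identical(nrow(voxelWeights(v1, "x")), 50L)
  expect_true(all(voxelWeights(v1, "x") >= 0))   # half-normal default
  expect_true(all(voxelWeights(v1, "z") >= 0))
  v3 <- makeVoxels(50, seed = 4)
  expect_false(identical(v1@weights, v3@weights))
  expect_error(makeVoxels(10, weightDistribution = "cauchy"),
    "unknown weight distribution")
})

test_that("noiseless trial responses equal the weighted channel activations", {
  vox <- makeVoxels(8, axes = "z", seed = 5)
  g <- makeGrid()
  tseq <- data.frame(row_index = c(1L, 4L, NA), col_index = c(2L, 5L, NA))
  B <- simulateTrialResponses(vox, g, tseq, noiseSd = 0)
  loc <- gridLocations(g)
  W <- voxelWeights(vox, "z")
  for (k in 1:2) {
    z <- loc$z_scene[loc$row_index == tseq$row_index[k] &
      loc$col_index == tseq$col_index[k]]
    act <- basisEval(abs(vox@centers$z - z), vox@size[["z"]])
    expect_equal(B[, k], as.vector(W %*% act))
  }
  expect_equal(B[, 3], rep(0, 8))   # null trial, zero noise
  expect_error(
    simulateTrialResponses(vox, g, data.frame(row_index = 9L, col_index = 1L)),
    "not present in the grid")
})

test_that("trial noise has the configured first and second moments", {
  vox <- makeVoxels(5, axes = "z", seed = 6)
  g <- makeGrid()
  tseq <- data.frame(row_index = rep(3L, 8000), col_index = rep(1L, 8000))
  B <- simulateTrialResponses(vox, g, tseq, noiseSd = 0.7, seed = 8)
  mu <- simulateTrialResponses(vox, g, tseq[1, , drop = FALSE], noiseSd = 0)
  # mean within 3 standard errors of the noiseless response
  se <- 0.7 / sqrt(8000)
  expect_true(all(abs(rowMeans(B) - mu[, 1]) < 3 * se))
  # per-voxel residual variance close to noiseSd^2
  expect_equal(mean(apply(B - as.vector(mu), 1, var)), 0.49,
    tolerance = 0.05)
})

test_that("the simulated experiment has the designed structure", {
  sim <- simulateExperiment(nSubjects = 2, nRuns = 4, nVoxels = 10, seed = 9)
  expect_identical(nSubjects(sim), 2L)
  info <- trialInfo(subjectData(sim, 1))
  expect_identical(unique(table(info$run)), 45L)      # 36 stimulus + 9 null
  expect_identical(as.vector(tapply(info$is_null, info$run, sum)), rep(9L, 4))
  # alternate runs mirrored (default: even-numbered)
  expect_identical(as.vector(tapply(info$mirrored, info$run, unique)),
    c(FALSE, TRUE, FALSE, TRUE))
  # each exact location appears nRuns/2 times per subject
  stim <- info[!info$is_null, ]
  expect_true(all(table(stim$x, stim$z) %in% c(0L, 2L)))
  expect_identical(sum(table(stim$x, stim$z) == 2L), 72L)
  # default design emulates nine subjects
  expect_identical(eval(formals(simulateExperiment)$nSubjects), 9L)
  expect_error(simulateExperiment(nRuns = 1), "at least two runs")
})

test_that("seeds alter the noise but not the design labels", {
  a <- simulateExperiment(nSubjects = 1, nRuns = 2, nVoxels = 6, seed = 10,
    noise = list(type = "absolute", sd = 1))
  b <- simulateExperiment(nSubjects = 1, nRuns = 2, nVoxels = 6, seed = 10,
    noise = list(type = "absolute", sd = 2))
  c <- simulateExperiment(nSubjects = 1, nRuns = 2, nVoxels = 6, seed = 10,
    noise = list(type = "absolute", sd = 1))
  expect_identical(trialInfo(subjectData(a, 1)), trialInfo(subjectData(b, 1)))
  expect_false(identical(trialResponses(subjectData(a, 1)),
    trialResponses(subjectData(b, 1))))
  expect_identical(trialResponses(subjectData(a, 1)),
    trialResponses(subjectData(c, 1)))
})
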