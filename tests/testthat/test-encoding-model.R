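test_that("the channel profile follows the exponentiated cosine exactly", {
  expect_identical(basisEval(0, 1.8), 1)
  expect_equal(basisEval(0.9, 1.8), 0.0078125)     # 0.5^7 at half size
  expect_identical(basisEval(1.8 * 1.2, 1.8), 0)   # compact support
  expect_identical(basisEval(1.8, 1.8), 0)         # support boundary closed
  expect_error(basisEval(1, -1), "must be > 0")
})

test_that("the basis tiles the axis with unit peaks and compact support", {
  b <- buildBasis()
  F <- basisMatrix(b)
  expect_identical(dim(F), c(6L, 111L))
  px <- pixelCoords(b)
  for (k in 1:6) {
    expect_equal(px[which.max(F[k, ])], basisCenters(b)[k])
    expect_equal(max(F[k, ]), 1)
    expect_true(all(F[k, abs(px - basisCenters(b)[k]) >= b@size] == 0))
    # support width = 2 * size
    on <- px[F[k, ] > 0]
    expect_lt(diff(range(on)), 2 * b@size + 1e-9)
  }
  expect_error(buildBasis(5, centers = seq(-1.5, 1.5, length.out = 6)),
    "must match")
})

test_that("stimulus profiles are normalized and respect the domain", {
  px <- PixelGrid()
  p <- stimulusProfile(0.3, px)                   # delta at a pixel center
  expect_identical(sum(p > 0), 1L)
  expect_equal(sum(p), 1)
  bc <- stimulusProfile(0.3, px, mode = "boxcar", extent = 0.65)
  expect_equal(sum(bc), 1)
  # pixel count on the fixed 0.05-spacing grid (extent = sphere radius)
  expect_identical(sum(bc > 0), as.integer(round(2 * 0.65 / 0.05)) + 1L)
  expect_error(stimulusProfile(3, px), "outside the pixel domain")
})

test_that("the design matrix is F S and linear in S", {
  b <- buildBasis()
  S1 <- stimulusProfileMatrix(c(-1.5, 0, 1.2), b@pixels)
  X1 <- designMatrix(b, S1)
  expect_identical(dim(X1), c(6L, 3L))
  j <- which(S1[, 2] == 1)
  expect_equal(X1[, 2], basisMatrix(b)[, j])
  S2 <- stimulusProfileMatrix(c(0.5, -0.7, 0.9), b@pixels)
  expect_equal(designMatrix(b, 2 * S1 + 3 * S2),
    2 * X1 + 3 * designMatrix(b, S2))
  expect_error(designMatrix(b, S1[-1, ]), "do not match")
})

test_that("weight estimation solves the least-squares problem", {
  # identity design: weights are the data
  B <- matrix(rnorm(18), 3)
  expect_equal(estimateWeights(B, diag(6)), B)
  # noiseless consistency: recover the generating weights exactly
  set.seed(21)
  W <- matrix(rnorm(8 * 6), 8)
  X <- matrix(runif(6 * 40), 6)
  expect_equal(estimateWeights(W %*% X, X), W, tolerance = 1e-10)
  # random instance vs per-voxel normal-equations oracle (stats::lm)
  set.seed(22)
  X <- matrix(rnorm(3 * 20), 3)
  B <- matrix(rnorm(5 * 20), 5)
  What <- estimateWeights(B, X)
  for (v in 1:5) {
    oracle <- coef(lm(B[v, ] ~ 0 + t(X)))
    expect_equal(unname(What[v, ]), unname(oracle), tolerance = 1e-10)
  }
  # rank-deficient design names the dead channels
  Xbad <- rbind(matrix(rnorm(2 * 30), 2), 0)
  expect_error(estimateWeights(matrix(rnorm(4 * 30), 4), Xbad),
    "rank deficient")
  expect_error(estimateWeights(B, X[, 1:2]), "same number of trials")
})

test_that("model inversion is the left pseudoinverse of the weights", {
  set.seed(23)
  W <- matrix(rnorm(10 * 4), 10)
  X2 <- matrix(rnorm(4 * 7), 4)
  expect_equal(invertModel(W, W %*% X2), X2, tolerance = 1e-10)
  # orthonormal weights: inversion reduces to the transpose
  Q <- qr.Q(qr(matrix(rnorm(10 * 4), 10)))
  B2 <- matrix(rnorm(10 * 5), 10)
  expect_equal(invertModel(Q, B2), t(Q) %*% B2, tolerance = 1e-12)
  # explicit pseudoinverse oracle on a small instance
  set.seed(24)
  W <- matrix(rnorm(4 * 2), 4)
  B2 <- matrix(rnorm(4 * 6), 4)
  expect_equal(invertModel(W, B2), pinvSvd(W) %*% B2, tolerance = 1e-10)
  expect_error(invertModel(cbind(W, W[, 1]), B2[1:4, ]), "rank deficient")
})

test_that("Eqs. of the weight/inversion path match a generic LS solver on
           random instances", {
  set.seed(25)
  for (i in 1:25) {
    nv <- sample(7:15, 1); nc <- sample(2:6, 1); nt <- sample(20:40, 1)
    X1 <- matrix(rnorm(nc * nt), nc)
    B1 <- matrix(rnorm(nv * nt), nv)
    What <- estimateWeights(B1, X1)
    expect_equal(What, B1 %*% pinvSvd(X1), tolerance = 1e-10)
    B2 <- matrix(rnorm(nv * 5), nv)
    expect_equal(invertModel(What, B2), pinvSvd(What) %*% B2,
      tolerance = 1e-10)
  }
})

test_that("reconstruction projects channel responses through the basis", {
  b <- buildBasis()
  X2hat <- diag(6)[, 1, drop = FALSE] * 2.5
  r <- reconstruct(X2hat, b)
  expect_equal(reconCurves(r)[1, ], 2.5 * basisMatrix(b)[1, ])
  expect_equal(reconCurves(reconstruct(matrix(0, 6, 2), b)),
    matrix(0, 2, 111))
  A <- matrix(rnorm(12), 6); B <- matrix(rnorm(12), 6)
  expect_equal(reconCurves(reconstruct(2 * A + B, b)),
    2 * reconCurves(reconstruct(A, b)) + reconCurves(reconstruct(B, b)))
})

test_that("cross-validated reconstruction visits every trial once and is
           exact on noiseless data", {
  sim <- noiselessExperiment("z")
  te <- subjectData(sim, 1)
  b <- buildBasis()
  rec <- crossvalReconstruct(te, b, axis = "z")
  info <- trialInfo(te)
  expect_identical(nrow(reconCurves(rec)), sum(!info$is_null))
  expect_false(anyNA(reconCurves(rec)))
  # round trip: every curve peaks at the true z within one pixel
  px <- pixelCoords(rec)
  peaks <- px[apply(reconCurves(rec), 1, which.max)]
  expect_true(all(abs(peaks - reconInfo(rec)$z) <= 0.05 + 1e-9))
  expect_error(crossvalReconstruct(
    TrialExperiment(trialResponses(te)[, info$run == 1],
      info[info$run == 1, ]), b, axis = "z"), "at least 2 runs")
})

test_that("reconstruction is linear in the test responses", {
  sim <- noiselessExperiment("z", nRuns = 2, nVoxels = 12, seed = 31)
  te <- subjectData(sim, 1)
  b <- buildBasis()
  info <- trialInfo(te)
  train <- !info$is_null & info$run == 1
  test <- !info$is_null & info$run == 2
  S <- stimulusProfileMatrix(info$z[train], b@pixels)
  W <- estimateWeights(trialResponses(te)[, train], designMatrix(b, S))
  B2 <- trialResponses(te)[, test]
  B2b <- B2 + matrix(rnorm(length(B2)), nrow(B2))
  r1 <- reconCurves(reconstruct(invertModel(W, B2), b))
  r2 <- reconCurves(reconstruct(invertModel(W, B2b), b))
  rsum <- reconCurves(reconstruct(invertModel(W, 2 * B2 + 3 * B2b), b))
  expect_equal(rsum, 2 * r1 + 3 * r2, tolerance = 1e-9)
})

test_that("duplicated runs make cross-validated and train-on-all
           reconstructions identical", {
  sim <- noiselessExperiment("z", nRuns = 2, nVoxels = 15, seed = 32)
  te <- subjectData(sim, 1)
  info <- trialInfo(te)
  # duplicate run 1 as run 2 so each fold trains on a copy of its test set
  i1 <- which(info$run == 1)
  B <- cbind(trialResponses(te)[, i1], trialResponses(te)[, i1])
  info2 <- rbind(info[i1, ], transform(info[i1, ], run = 2))
  te2 <- TrialExperiment(B, info2)
  b <- buildBasis()
  cv <- crossvalReconstruct(te2, b, axis = "z")
  keep <- !info2$is_null
  S <- stimulusProfileMatrix(info2$z[keep], b@pixels)
  W <- estimateWeights(B[, keep], designMatrix(b, S))
  full <- reconstruct(invertModel(W, B[, keep]), b)
  expect_equal(reconCurves(cv), reconCurves(full), tolerance = 1e-8)
})

test_that("position averaging folds mirrored runs onto six positions", {
  sim <- noiselessExperiment("x", nRuns = 4, nVoxels = 20, seed = 33)
  te <- subjectData(sim, 1)
  b <- buildBasis()
  rec <- crossvalReconstruct(te, b, axis = "x")
  avg <- averageByPosition(rec)
  expect_identical(nrow(reconCurves(avg)), 6L)
  info <- reconInfo(avg)
  expect_true(all(diff(info$true_coord) > 0))
  expect_identical(sum(info$n_trials), nrow(reconCurves(rec)))
  # curves peak at the folded column coordinate within one pixel + stagger
  px <- pixelCoords(avg)
  peaks <- px[apply(reconCurves(avg), 1, which.max)]
  expect_true(all(abs(peaks - info$true_coord) < 0.31))
  # reflecting a curve matrix twice is the identity
  m <- reconCurves(rec)
  expect_identical(m[, rev(rev(seq_len(ncol(m))))], m)
})

test_that("mirroring the stimulus yields pixel-reflected reconstructions", {
  # voxels tuned along x; mirroring tuning and stimuli together must
  # reflect the recovered curves about the domain midpoint
  g <- makeGrid()
  gm <- makeGrid(mirrored = TRUE)
  tseq <- data.frame(
    row_index = rep(1:6, each = 6), col_index = rep(1:6, 6))
  vox <- makeVoxels(25, axes = "x", seed = 34)
  voxM <- vox
  voxM@weights$x <- vox@weights$x[, 6:1]   # mirror tuning (centers symmetric)
  B1 <- simulateTrialResponses(vox, g, tseq, noiseSd = 0)
  B2 <- simulateTrialResponses(voxM, gm, tseq, noiseSd = 0)
  b <- buildBasis()
  info <- attr(B1, "info")
  S1 <- stimulusProfileMatrix(attr(B1, "info")$x, b@pixels)
  S2 <- stimulusProfileMatrix(attr(B2, "info")$x, b@pixels)
  W1 <- estimateWeights(B1, designMatrix(b, S1))
  W2 <- estimateWeights(B2, designMatrix(b, S2))
  r1 <- reconCurves(reconstruct(invertModel(W1, B1), b))
  r2 <- reconCurves(reconstruct(invertModel(W2, B2), b))
  expect_equal(r2, r1[, rev(seq_len(ncol(r1)))], tolerance = 1e-8)
})
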