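test_that("the pairwise scheme enumerates all 15 depth comparisons", {
  sch <- pairwiseScheme()
  expect_identical(nrow(sch), 15L)
  expect_true(all(sch$delta_disparity_arcmin > 0))
  expect_identical(anyDuplicated(sch[c("pair_i", "pair_j")]), 0L)
  # the two largest published separations
  expect_equal(sort(sch$delta_disparity_arcmin, decreasing = TRUE)[1:2],
    c(83.2, 70.2))
})

test_that("d-prime reproduces hand-computed signal-detection values", {
  expect_equal(dprime(0.8, 0.2, 100), qnorm(0.8) - qnorm(0.2))
  expect_equal(dprime(0.8, 0.2, 100), 1.683, tolerance = 0.001 / 1.683)
  expect_identical(dprime(0.5, 0.5, 10), 0)
  expect_equal(dprime(0.37, 0.37, 50), 0)
  # perfect rates are clipped at 1/(2N)
  expect_equal(dprime(1, 0, 10), 2 * qnorm(0.95))
  expect_equal(dprime(1, 0, 10), 3.290, tolerance = 0.001)
  expect_error(dprime(1.2, 0, 10), "rates must lie")
})

test_that("well-separated classes decode at high accuracy, deterministically", {
  sim <- noisyExperiment(rel = 0.1, nRuns = 4, nVoxels = 40, seed = 51)
  te <- subjectData(sim, 1)
  r1 <- pairwiseDecode(te, 1, 6)
  expect_gt(r1$accuracy, 0.9)
  expect_identical(r1, pairwiseDecode(te, 1, 6))
  expect_identical(r1$nPerClass, 24L)   # 6 trials per run per row x 4 runs
  expect_error(pairwiseDecode(te, 1, 7), "must be present")
})

test_that("shuffled labels remove the decodable signal", {
  sim <- noisyExperiment(rel = 0.1, nRuns = 4, nVoxels = 40, seed = 52)
  te <- subjectData(sim, 1)
  null <- permutationNull(te, 1, 6, nIter = 60, seed = 53)
  expect_length(null, 60L)
  expect_identical(null, permutationNull(te, 1, 6, nIter = 60, seed = 53))
  # null is centred on zero
  expect_lt(abs(mean(null)), 3 * sd(null) / sqrt(length(null)) + 0.05)
  # a single shuffled decode falls inside the null's 95% band
  info <- trialInfo(te)
  keep <- !info$is_null & info$row_index %in% c(1, 6)
  shuffled <- withr::with_seed(54, sample(info$row_index[keep]))
  dShuf <- pairwiseDecode(te, 1, 6, labels = shuffled)$dprime
  expect_gte(dShuf, quantile(null, 0.025) - 1e-9)
  expect_lte(dShuf, quantile(null, 0.975) + 1e-9)
  expect_error(permutationNull(te, 1, 6, nIter = 0), "nIter")
})

test_that("six-way decoding averages the 15 pairwise comparisons", {
  sim <- noisyExperiment(rel = 0.3, nRuns = 4, nVoxels = 30, seed = 55)
  te <- subjectData(sim, 1)
  tab <- sixWayDecode(te)
  expect_identical(nrow(tab), 15L)
  d16 <- pairwiseDecode(te, 1, 6)$dprime
  expect_equal(tab$dprime[tab$pair_i == 1 & tab$pair_j == 6], d16)
  expect_equal(mean(tab$dprime),
    mean(vapply(seq_len(15), function(k)
      pairwiseDecode(te, tab$pair_i[k], tab$pair_j[k])$dprime, 0)))
})

test_that("the group permutation p-value is the minimum tail proportion", {
  real <- c(0.5, 0.7, 0.6)
  nullAbove <- matrix(rnorm(3 * 200, mean = 5), 3)
  expect_identical(groupPermutationPvalue(real, nullAbove), 0)
  expect_equal(groupPermutationPvalue(real, nullAbove, smooth = TRUE),
    1 / 201)
  # real at the null median: p around one half
  nullMid <- matrix(rep(seq(-1, 2.2, length.out = 200), each = 3), 3)
  expect_equal(groupPermutationPvalue(real, nullMid), 0.5, tolerance = 0.02)
  # negating everything leaves p unchanged
  nullAny <- matrix(rnorm(3 * 500), 3)
  expect_identical(groupPermutationPvalue(real, nullAny),
    groupPermutationPvalue(-real, -nullAny))
  expect_error(groupPermutationPvalue(real, nullAny[1:2, ]), "same subjects")
})

test_that("Benjamini-Hochberg matches the hand-computed step-up", {
  # thresholds k q / m = 0.0125, 0.025, 0.0375, 0.05: reject first three
  expect_identical(fdrBh(c(0.001, 0.02, 0.03, 0.5), 0.05),
    c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdrBh(rep(1, 6), 0.05), rep(FALSE, 6))
  expect_identical(fdrBh(numeric(0)), logical(0))
  # rejections at the stricter level are a subset
  set.seed(56)
  p <- runif(40)^2
  expect_true(all(which(fdrBh(p, 0.01)) %in% which(fdrBh(p, 0.05))))
  expect_error(fdrBh(c(0.2, 1.4)), "must lie")
})

test_that("the d-prime/disparity slope matches a closed-form OLS oracle", {
  sch <- pairwiseScheme()
  dd <- sch$delta_disparity_arcmin
  # exactly linear data: slope and intercept recovered, all iterations equal
  dMat <- rbind(0.01 * dd + 0.2, 0.01 * dd + 0.2)
  sl <- dprimeDisparitySlope(dMat, dd, nBoot = 50, seed = 57)
  expect_equal(sl$slope, 0.01, tolerance = 1e-12)
  expect_equal(sl$intercept, 0.2, tolerance = 1e-12)
  expect_equal(unname(sl$ci), c(0.01, 0.01), tolerance = 1e-12)
  # constant d-prime: slope zero
  expect_equal(dprimeDisparitySlope(rbind(rep(1, 15), rep(1, 15)), dd,
    nBoot = 10, seed = 1)$slope, 0)
  # random case vs lm oracle
  set.seed(58)
  dMat <- matrix(rnorm(5 * 15, mean = 0.3), 5)
  sl <- dprimeDisparitySlope(dMat, dd, nBoot = 10, seed = 59)
  oracle <- coef(lm(colMeans(dMat) ~ dd))
  expect_equal(sl$slope, unname(oracle[2]), tolerance = 1e-10)
  expect_equal(sl$intercept, unname(oracle[1]), tolerance = 1e-10)
  expect_error(dprimeDisparitySlope(dMat, rep(1, 15)), "degenerate")
})
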