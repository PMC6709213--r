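#' Pairwise depth comparison scheme
#'
#' All `C(6, 2) = 15` unordered pairs of the six depth rows, each with its
#' depth separation `delta_disparity_arcmin` (absolute difference of the
#' row-average disparities, by default the published values of
#' [depthRowDisparities()]).
#'
#' @param rowTable data.frame with `z_scene` and `disparity_arcmin`, one
#'   row per depth row in grid order.
#' @return data.frame with columns `pair_i`, `pair_j` (row indices),
#'   `z_i`, `z_j`, `delta_disparity_arcmin`.
#' @examples
#' nrow(pairwiseScheme())                       # 15
#' max(pairwiseScheme()$delta_disparity_arcmin) # 83.2
#' @export
pairwiseScheme <- function(rowTable = depthRowDisparities()) {
  pairs <- which(upper.tri(diag(nrow(rowTable))), arr.ind = TRUE)
  out <- data.frame(
    pair_i = pairs[, "row"], pair_j = pairs[, "col"],
    z_i = rowTable$z_scene[pairs[, "row"]],
    z_j = rowTable$z_scene[pairs[, "col"]],
    delta_disparity_arcmin = abs(rowTable$disparity_arcmin[pairs[, "col"]] -
      rowTable$disparity_arcmin[pairs[, "row"]]))
  out[order(out$pair_i, out$pair_j), , drop = FALSE]
}

#' Sensitivity index d-prime from hit and false-alarm rates
#'
#' `qnorm(HR) - qnorm(FAR)` after clipping both rates to
#' `[1/(2N), 1 - 1/(2N)]` so that perfect rates stay finite (the standard
#' extreme-rate correction; `N` is the number of trials per class).
#'
#' @param hitRate,faRate rates in \[0, 1\].
#' @param nPerClass trials per class used to form the rates.
#' @return d-prime (unitless).
#' @examples
#' dprime(0.8, 0.2, 100)     # 1.683
#' dprime(1, 0, 10)          # 2 * qnorm(0.95) = 3.290
#' @export
dprime <- function(hitRate, faRate, nPerClass) {
  if (any(c(hitRate, faRate) < 0 | c(hitRate, faRate) > 1))
    stop("rates must lie in [0, 1]")
  if (any(nPerClass < 1)) stop("nPerClass must be >= 1")
  eps <- 1 / (2 * nPerClass)
  qnorm(clamp(hitRate, eps, 1 - eps)) - qnorm(clamp(faRate, eps, 1 - eps))
}

# leave-one-run-out linear-SVM decode of two depth rows; y/runs/X already
# restricted to the two classes. Returns pooled predictions.
decodeFolds <- function(X, y, runs, cost, tolerance = 0.01) {
  preds <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (r in unique(runs)) {
    test <- runs == r
    if (length(unique(y[!test])) < 2L) {
      warning("run ", r, " cannot be held out: training set lacks a class; ",
        "fold skipped")
      next
    }
    # standardize features on the training fold (real trial estimates are
    # z-scored; this keeps the classifier invariant to simulation scale and
    # well-conditioned at low SNR)
    fit <- svm(X[!test, , drop = FALSE], y[!test], kernel = "linear",
      cost = cost, scale = TRUE, type = "C-classification",
      tolerance = tolerance)
    preds[test] <- predict(fit, X[test, , drop = FALSE])
  }
  preds
}

#' Pairwise decoding of two depth rows
#'
#' Restricts the dataset to trials of two depth rows (collapsing across
#' horizontal position within each row), trains a linear maximum-margin
#' classifier under leave-one-run-out cross-validation, pools the held-out
#' predictions, and scores them with [dprime()] (row `posI` treated as the
#' signal class) and raw accuracy.
#'
#' @param te a [TrialExperiment-class].
#' @param posI,posJ depth row indices (1..6) to discriminate.
#' @param cost the classifier regularization constant.
#' @param tolerance solver stopping tolerance of the margin optimizer.
#' @param labels optional replacement class labels (used by the permutation
#'   machinery); must have one entry per restricted trial.
#' @return list with `dprime`, `accuracy`, `hitRate`, `faRate`,
#'   `nPerClass`, `n`.
#' @export
pairwiseDecode <- function(te, posI, posJ, cost = 1, tolerance = 0.01,
                           labels = NULL) {
  info <- trialInfo(te)
  keep <- !info$is_null & info$row_index %in% c(posI, posJ)
  if (!any(info$row_index %in% posI, na.rm = TRUE) ||
      !any(info$row_index %in% posJ, na.rm = TRUE))
    stop("both depth rows must be present in the dataset")
  X <- t(trialResponses(te)[, keep, drop = FALSE])
  y <- factor(info$row_index[keep], levels = c(posI, posJ))
  if (!is.null(labels)) y <- factor(labels, levels = c(posI, posJ))
  runs <- info$run[keep]
  preds <- decodeFolds(X, y, runs, cost, tolerance)
  ok <- !is.na(preds)
  isI <- y == posI
  hr <- mean(preds[ok & isI] == posI)
  fa <- mean(preds[ok & !isI] == posI)
  nI <- sum(ok & isI); nJ <- sum(ok & !isI)
  list(dprime = dprime(hr, fa, min(nI, nJ)),
    accuracy = mean(preds[ok] == y[ok]),
    hitRate = hr, faRate = fa, nPerClass = min(nI, nJ), n = sum(ok))
}

#' Decode all 15 depth-row pairs
#'
#' Applies [pairwiseDecode()] to every pair of the scheme. The mean of the
#' 15 pairwise d-primes is the six-way decoding score.
#'
#' @param te a [TrialExperiment-class].
#' @param scheme a [pairwiseScheme()].
#' @param cost classifier regularization constant.
#' @return the scheme data.frame with added `dprime` and `accuracy`.
#' @export
sixWayDecode <- function(te, scheme = pairwiseScheme(), cost = 1,
                         tolerance = 0.01) {
  res <- lapply(seq_len(nrow(scheme)), function(k)
    pairwiseDecode(te, scheme$pair_i[k], scheme$pair_j[k], cost = cost,
      tolerance = tolerance))
  scheme$dprime <- vapply(res, `[[`, 0, "dprime")
  scheme$accuracy <- vapply(res, `[[`, 0, "accuracy")
  scheme
}

#' Permutation null distribution for one pairwise decode
#'
#' Repeats the full cross-validated decode after uniformly shuffling the
#' class labels across all trials of the restricted two-row dataset. The
#' resulting d-primes form the null distribution of no label-response
#' coupling.
#'
#' @inheritParams pairwiseDecode
#' @param nIter number of shuffling iterations (>= 1).
#' @param seed integer seed; the null is reproducible from it.
#' @return numeric vector of `nIter` null d-primes.
#' @export
permutationNull <- function(te, posI, posJ, nIter = 1000L, seed = 1L,
                            cost = 1, tolerance = 0.01) {
  if (nIter < 1L) stop("nIter must be >= 1")
  info <- trialInfo(te)
  keep <- !info$is_null & info$row_index %in% c(posI, posJ)
  truth <- info$row_index[keep]
  vapply(seq_len(nIter), function(it) {
    shuffled <- with_seed(childSeed(seed, it), sample(truth))
    pairwiseDecode(te, posI, posJ, cost = cost, tolerance = tolerance,
      labels = shuffled)$dprime
  }, 0)
}

#' Group-level permutation p-value
#'
#' Compares the subject-averaged real d-prime against the distribution of
#' subject-averaged shuffled d-primes: the p-value is the smaller of the
#' two tail proportions (share of iterations with null >= real, and share
#' with real >= null). With `smooth = TRUE` the add-one estimate
#' `(count + 1) / (nIter + 1)` is used so p is never exactly 0.
#'
#' @param realD per-subject real d-primes.
#' @param nullD subjects x iterations matrix of null d-primes (or a vector
#'   for a single subject).
#' @param smooth use the add-one tail estimate.
#' @return the p-value.
#' @export
groupPermutationPvalue <- function(realD, nullD, smooth = FALSE) {
  if (is.vector(nullD)) nullD <- matrix(nullD, nrow = 1)
  if (!ncol(nullD)) stop("empty null distribution")
  if (nrow(nullD) != length(realD))
    stop("realD and nullD must cover the same subjects")
  mReal <- mean(realD)
  mNull <- colMeans(nullD)
  hi <- sum(mNull >= mReal)
  lo <- sum(mReal >= mNull)
  if (smooth) min(hi + 1, lo + 1) / (length(mNull) + 1)
  else min(hi, lo) / length(mNull)
}

#' Benjamini-Hochberg FDR rejection flags
#'
#' Step-up false-discovery-rate control over a flat vector of p-values
#' (e.g. the full table of all region-by-comparison tests), at level `q`.
#'
#' @param pvalues p-values in \[0, 1\].
#' @param q FDR level.
#' @return logical rejection flags, same length as `pvalues`.
#' @examples
#' fdrBh(c(0.001, 0.02, 0.03, 0.5), 0.05)  # TRUE TRUE TRUE FALSE
#' @export
fdrBh <- function(pvalues, q = 0.05) {
  if (!length(pvalues)) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH") <= q
}

#' Slope of the d-prime versus disparity-difference relationship
#'
#' Bootstraps subjects (resampling with replacement), computes the
#' subject-mean d-prime per pair on each iteration, and fits an ordinary
#' least-squares line of d-prime on the disparity difference. Reports the
#' point estimate (on the original subject mean), percentile CI, a
#' two-tailed t test of the slope distribution against zero, and the
#' tail-proportion p-value of the distribution against zero.
#'
#' @param dMat subjects x pairs matrix of d-primes.
#' @param deltaDisp disparity differences (arcmin), one per pair.
#' @param nBoot bootstrap iterations.
#' @param seed integer seed.
#' @return list with `slope`, `intercept`, `ci`, `slopes` (the bootstrap
#'   distribution), `pTTest`, `pBoot`.
#' @export
dprimeDisparitySlope <- function(dMat, deltaDisp, nBoot = 1000L, seed = 1L) {
  dMat <- as.matrix(dMat)
  if (ncol(dMat) != length(deltaDisp))
    stop("one disparity difference per pair is required")
  if (var(deltaDisp) == 0)
    stop("disparity differences are degenerate (all equal)")
  olsLine <- function(y) {
    b <- cov(deltaDisp, y) / var(deltaDisp)
    c(slope = b, intercept = mean(y) - b * mean(deltaDisp))
  }
  point <- olsLine(colMeans(dMat))
  n <- nrow(dMat)
  boots <- with_seed(as.integer(seed), {
    t(vapply(seq_len(nBoot), function(i) {
      olsLine(colMeans(dMat[sample.int(n, n, replace = TRUE), , drop = FALSE]))
    }, numeric(2)))
  })
  list(slope = unname(point["slope"]), intercept = unname(point["intercept"]),
    ci = unname(quantile(boots[, 1], c(0.025, 0.975))),
    slopes = boots[, 1],
    pTTest = if (var(boots[, 1]) > 0) t.test(boots[, 1], mu = 0)$p.value else 0,
    pBoot = min(mean(boots[, 1] <= 0), mean(boots[, 1] >= 0)))
}
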