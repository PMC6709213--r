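#' Bootstrap a statistic across subjects
#'
#' Resamples subjects with replacement `nIter` times and applies the
#' statistic to each resample, yielding an empirical estimate of the
#' between-subject variability with percentile confidence bounds. The
#' point estimate is the statistic on the original sample.
#'
#' @param perSubject per-subject values: a numeric vector (one value per
#'   subject) or a subjects x k matrix.
#' @param statistic function mapping a resampled vector/matrix to one or
#'   more numbers (default: the subject mean / column means).
#' @param nIter number of resampling iterations.
#' @param seed integer seed.
#' @param level confidence level for the percentile interval.
#' @return a [BootstrapDistribution-class].
#' @examples
#' b <- bootstrapSubjects(c(1, 2, 3, 10), nIter = 500, seed = 1)
#' bootCI(b)
#' @export
bootstrapSubjects <- function(perSubject, statistic = NULL, nIter = 1000L,
                              seed = 1L, level = 0.95) {
  isVec <- !is.matrix(perSubject)
  mat <- if (isVec) matrix(perSubject, ncol = 1) else perSubject
  if (!nrow(mat)) stop("at least one subject is required")
  statistic <- statistic %||% (if (isVec) mean else colMeans)
  apply1 <- function(m) as.numeric(statistic(if (isVec) m[, 1] else m))
  point <- apply1(mat)
  n <- nrow(mat)
  vals <- with_seed(as.integer(seed), {
    v <- vapply(seq_len(nIter), function(i)
      apply1(mat[sample.int(n, n, replace = TRUE), , drop = FALSE]),
      numeric(length(point)))
    if (is.matrix(v)) t(v) else matrix(v, ncol = 1)
  })
  alpha <- (1 - level) / 2
  ci <- apply(vals, 2, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  ci <- matrix(ci, nrow = 2)
  nm <- names(statistic(if (isVec) mat[, 1] else mat)) %||% colnames(mat)
  if (!is.null(nm)) names(point) <- nm
  new("BootstrapDistribution", values = vals, point = point,
    ciLower = ci[1, ], ciUpper = ci[2, ], level = level,
    nIter = as.integer(nIter), seed = as.integer(seed))
}

#' Slope of fitted centers on true stimulus positions
#'
#' Ordinary least-squares line of the six fitted representation centers on
#' the six displayed coordinates. A slope of 1 indicates perfect position
#' recovery; a slope of 0 indicates that the encoding model carries no
#' position information.
#'
#' @param fitCenters fitted centers (scene units).
#' @param truePositions displayed coordinates (scene units).
#' @return named numeric: `slope`, `intercept`.
#' @examples
#' centerVsTrueSlope(c(-1, 0, 1), c(-1, 0, 1))   # slope 1, intercept 0
#' @export
centerVsTrueSlope <- function(fitCenters, truePositions) {
  if (length(fitCenters) != length(truePositions) || length(fitCenters) < 2)
    stop("need matched vectors of at least 2 positions")
  if (var(truePositions) == 0)
    stop("true positions are degenerate (all equal)")
  slope <- cov(truePositions, fitCenters) / var(truePositions)
  c(slope = slope, intercept = mean(fitCenters) - slope * mean(truePositions))
}

#' Bootstrap the center-versus-true slope across subjects
#'
#' Resamples subjects, averages their fitted centers per position, and fits
#' the [centerVsTrueSlope()] line on every iteration, so the slope CI
#' reflects between-subject variability.
#'
#' @param centersMat subjects x positions matrix of fitted centers.
#' @param truePositions displayed coordinate per position.
#' @param nIter,seed,level see [bootstrapSubjects()].
#' @return a [BootstrapDistribution-class] over `(slope, intercept)`.
#' @export
bootstrapCenterSlope <- function(centersMat, truePositions, nIter = 1000L,
                                 seed = 1L, level = 0.95) {
  bootstrapSubjects(as.matrix(centersMat),
    statistic = function(m) centerVsTrueSlope(colMeans(m), truePositions),
    nIter = nIter, seed = seed, level = level)
}

#' Tail-proportion p-value of a distribution against zero
#'
#' The smaller of the two tail proportions (share of values <= 0 and share
#' >= 0), matching the permutation convention of
#' [groupPermutationPvalue()]. `smooth = TRUE` uses the add-one estimate.
#'
#' @param dist a [BootstrapDistribution-class] or numeric vector; for a
#'   multi-statistic distribution the first statistic is used.
#' @param smooth use `(count + 1) / (n + 1)`.
#' @return the p-value.
#' @export
distributionPvalueVsZero <- function(dist, smooth = FALSE) {
  v <- if (is(dist, "BootstrapDistribution")) bootValues(dist)[, 1] else dist
  if (!length(v)) stop("empty distribution")
  lo <- sum(v <= 0)
  hi <- sum(v >= 0)
  if (smooth) min(lo + 1, hi + 1) / (length(v) + 1)
  else min(lo, hi) / length(v)
}

#' Paired comparison of two bootstrap distributions
#'
#' Per-iteration differences of two distributions generated with a common
#' resampling pairing, scored with the two-tail minimum-proportion rule
#' against zero.
#'
#' @param distA,distB [BootstrapDistribution-class] objects (or numeric
#'   vectors) with equal iteration counts.
#' @param smooth use the add-one estimate.
#' @return the p-value of the difference.
#' @export
pairwiseGroupDiff <- function(distA, distB, smooth = FALSE) {
  a <- if (is(distA, "BootstrapDistribution")) bootValues(distA)[, 1] else distA
  b <- if (is(distB, "BootstrapDistribution")) bootValues(distB)[, 1] else distB
  if (length(a) != length(b))
    stop("distributions must have the same number of iterations")
  distributionPvalueVsZero(a - b, smooth = smooth)
}
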