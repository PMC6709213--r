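#' Channel design matrix for a set of trials
#'
#' `X1 = F S`: the predicted activation of each channel on each trial, given
#' the basis sampled on the pixel grid (`F`, channels x pixels) and the
#' pixel representation of the stimulus on each trial (`S`, pixels x
#' trials).
#'
#' @param basis a [SpatialBasis-class] (or a channels x pixels matrix).
#' @param S pixels x trials stimulus profile matrix
#'   (see [stimulusProfileMatrix()]).
#' @return channels x trials design matrix.
#' @export
designMatrix <- function(basis, S) {
  F <- if (is(basis, "SpatialBasis")) basisMatrix(basis) else as.matrix(basis)
  S <- as.matrix(S)
  if (ncol(F) != nrow(S))
    stop("pixel dimensions of the basis (", ncol(F),
      ") and stimulus profiles (", nrow(S), ") do not match")
  F %*% S
}

#' Estimate channel-to-voxel weights
#'
#' Least-squares solution of the forward model `B1 = W X1` for the weight
#' matrix: `What = B1 X1' (X1 X1')^-1`, the Moore-Penrose pseudoinverse
#' solution when `X1` (channels x trials) has full row rank. `B1` is the
#' training matrix of voxel responses (voxels x trials).
#'
#' @param B1 voxels x trials training responses (matrix or
#'   [TrialExperiment-class], in which case non-null trials are used and the
#'   caller must supply a matching `X1`).
#' @param X1 channels x trials design matrix from [designMatrix()].
#' @return voxels x channels weight matrix.
#' @export
estimateWeights <- function(B1, X1) {
  if (is(B1, "TrialExperiment")) B1 <- trialResponses(B1)
  B1 <- as.matrix(B1); X1 <- as.matrix(X1)
  if (ncol(B1) != ncol(X1))
    stop("B1 and X1 must have the same number of trials")
  if (ncol(X1) < nrow(X1))
    stop("need at least as many trials as channels")
  G <- tcrossprod(X1)                      # channels x channels
  qrG <- qr(G)
  if (qrG$rank < nrow(X1)) {
    bad <- setdiff(seq_len(nrow(X1)), sort(qrG$pivot[seq_len(qrG$rank)]))
    stop("design matrix is rank deficient; channel(s) ",
      paste(bad, collapse = ", "),
      " are not independently stimulated by the training trials")
  }
  t(solve(G, X1 %*% t(B1)))
}

#' Invert the encoding model on held-out data
#'
#' Estimated channel responses for test trials: `X2hat = (W'W)^-1 W' B2`,
#' the left pseudoinverse of the estimated weight matrix applied to the
#' voxels x trials test responses.
#'
#' @param W voxels x channels weight matrix from [estimateWeights()].
#' @param B2 voxels x trials test responses (matrix or
#'   [TrialExperiment-class]).
#' @return channels x trials matrix of estimated channel responses.
#' @export
invertModel <- function(W, B2) {
  if (is(B2, "TrialExperiment")) B2 <- trialResponses(B2)
  W <- as.matrix(W); B2 <- as.matrix(B2)
  if (nrow(W) != nrow(B2))
    stop("W and B2 must have the same number of voxels")
  if (nrow(W) < ncol(W))
    stop("need at least as many voxels as channels")
  G <- crossprod(W)
  if (qr(G)$rank < ncol(W))
    stop("estimated weight matrix is rank deficient; cannot invert")
  solve(G, crossprod(W, B2))
}

#' Project channel responses into pixel space
#'
#' Multiplies estimated channel responses through the basis to yield the
#' model-based representation of each trial: a trials x pixels matrix of
#' curves (`X2hat' F`).
#'
#' @param X2hat channels x trials matrix from [invertModel()].
#' @param basis the [SpatialBasis-class] used to build the design matrix.
#' @param info optional data.frame of per-trial labels.
#' @return a [Reconstruction-class].
#' @export
reconstruct <- function(X2hat, basis, info = NULL) {
  X2hat <- as.matrix(X2hat)
  F <- basisMatrix(basis)
  if (nrow(X2hat) != nrow(F))
    stop("channel dimensions of X2hat and the basis do not match")
  new("Reconstruction", curves = t(X2hat) %*% F, pixels = basis@pixels,
    info = info %||% data.frame())
}

#' Cross-validated model-based reconstruction
#'
#' Runs the full inverted-encoding-model loop with leave-one-run-out
#' cross-validation: for each run, channel weights are estimated from all
#' other runs ([estimateWeights()]) and inverted on the held-out run
#' ([invertModel()]), so every stimulus trial is reconstructed exactly once
#' from independent training data. Null trials are excluded.
#'
#' @param te a [TrialExperiment-class].
#' @param basis a [SpatialBasis-class].
#' @param axis which stimulus coordinate to model: `"x"` or `"z"`.
#' @param profileMode,extent stimulus profile settings
#'   (see [stimulusProfile()]).
#' @return a [Reconstruction-class] with one curve per non-null trial; its
#'   `info` carries the trial metadata.
#' @export
crossvalReconstruct <- function(te, basis, axis = c("z", "x"),
                                profileMode = c("delta", "boxcar"),
                                extent = NULL) {
  axis <- match.arg(axis)
  profileMode <- match.arg(profileMode)
  info <- trialInfo(te)
  keep <- !info$is_null
  B <- trialResponses(te)[, keep, drop = FALSE]
  info <- info[keep, , drop = FALSE]
  runs <- unique(info$run)
  if (length(runs) < 2L)
    stop("leave-one-run-out cross-validation needs at least 2 runs")
  coords <- info[[axis]]
  S <- stimulusProfileMatrix(coords, basis@pixels, profileMode, extent)
  X <- designMatrix(basis, S)
  curves <- matrix(NA_real_, nrow = ncol(B), ncol = basis@pixels@n)
  for (r in runs) {
    testIdx <- which(info$run == r)
    trainIdx <- which(info$run != r)
    W <- estimateWeights(B[, trainIdx, drop = FALSE],
      X[, trainIdx, drop = FALSE])
    X2hat <- invertModel(W, B[, testIdx, drop = FALSE])
    curves[testIdx, ] <- t(X2hat) %*% basisMatrix(basis)
  }
  new("Reconstruction", curves = curves, pixels = basis@pixels,
    info = cbind(info, axis = axis))
}

#' Average reconstructions within stimulus positions
#'
#' Collapses per-trial reconstructions to the six mean position curves. For
#' the horizontal (`x`) axis, curves from mirrored runs are first reflected
#' about the domain midpoint so that mirrored trials line up with the base
#' columns, then curves are averaged within `col_index`; the reported true
#' coordinate of each column is the mean (reflection-corrected) stimulus x.
#' For the depth (`z`) axis no reflection is needed and averaging is within
#' `row_index`, with the row z as true coordinate.
#'
#' @param recon a per-trial [Reconstruction-class] from
#'   [crossvalReconstruct()].
#' @param axis `"x"` or `"z"`; defaults to the axis the reconstruction was
#'   built for.
#' @return a [Reconstruction-class] with 6 curves; `info` has columns
#'   `position` (index), `true_coord` and `n_trials`.
#' @export
averageByPosition <- function(recon, axis = NULL) {
  info <- reconInfo(recon)
  axis <- axis %||% unique(info$axis)
  if (length(axis) != 1L || !axis %in% c("x", "z"))
    stop("axis must be \"x\" or \"z\"")
  curves <- reconCurves(recon)
  coords <- info[[axis]]
  if (axis == "x") {
    flip <- as.logical(info$mirrored)
    # reflect mirrored-run curves about the (symmetric) domain midpoint
    curves[flip, ] <- curves[flip, rev(seq_len(ncol(curves))), drop = FALSE]
    coords[flip] <- -coords[flip]
    groups <- info$col_index
  } else {
    groups <- info$row_index
  }
  levs <- sort(unique(groups))
  if (length(levs) != 6L)
    stop("expected 6 stimulus positions along the ", axis, " axis, found ",
      length(levs))
  out <- t(vapply(levs, function(g) {
    idx <- which(groups == g)
    if (!length(idx)) stop("empty position cell: ", g)
    colMeans(curves[idx, , drop = FALSE])
  }, numeric(ncol(curves))))
  trueCoord <- vapply(levs, function(g) mean(coords[groups == g]), 0)
  nTrials <- vapply(levs, function(g) sum(groups == g), 0L)
  new("Reconstruction", curves = out, pixels = recon@pixels,
    info = data.frame(position = levs, true_coord = trueCoord,
      n_trials = nTrials, axis = axis))
}
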