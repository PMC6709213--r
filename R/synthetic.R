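#' Draw a ground-truth voxel population
#'
#' Creates voxels with known spatial tuning. Each voxel's tuning along an
#' axis is a fixed mixture of generative exponentiated-cosine channels;
#' weights are drawn independently per voxel and channel from the requested
#' distribution (default: half-normal, so all weights are nonnegative). The
#' generative channels default to the analysis basis (6 channels at the
#' stimulus row coordinates, size 1.8) but can be configured to differ, to
#' probe robustness to basis mismatch.
#'
#' @param nVoxels number of voxels (>= 1).
#' @param axes which stimulus axes the voxels are tuned to (any of `"x"`,
#'   `"z"`); multi-axis tuning is additive.
#' @param centers generative channel centers (shared across axes, or a
#'   named list per axis).
#' @param size generative channel size, scene units.
#' @param exponent generative cosine exponent.
#' @param weightDistribution `"halfnormal"`, `"normal"` or `"uniform"`.
#' @param weightScale scale of the weight distribution.
#' @param seed integer seed; the population is a pure function of the
#'   arguments and this seed.
#' @return a [VoxelPopulation-class].
#' @examples
#' vp <- makeVoxels(20, seed = 1)
#' dim(voxelWeights(vp, "z"))   # 20 x 6
#' @export
makeVoxels <- function(nVoxels, axes = c("x", "z"),
                       centers = seq(-1.5, 1.5, length.out = 6),
                       size = 1.8, exponent = 7,
                       weightDistribution = "halfnormal",
                       weightScale = 1, seed = 1L) {
  if (nVoxels < 1L) stop("nVoxels must be >= 1")
  if (!is.list(centers)) centers <- setNames(rep(list(centers), length(axes)), axes)
  draw <- switch(weightDistribution,
    halfnormal = function(n) abs(rnorm(n, sd = weightScale)),
    normal = function(n) rnorm(n, sd = weightScale),
    uniform = function(n) runif(n, 0, weightScale),
    stop("unknown weight distribution: ", weightDistribution))
  weights <- with_seed(as.integer(seed), {
    lapply(setNames(axes, axes), function(ax)
      matrix(draw(nVoxels * length(centers[[ax]])), nrow = nVoxels))
  })
  new("VoxelPopulation", weights = weights, centers = centers[axes],
    size = setNames(rep(size, length.out = length(axes)), axes),
    exponent = exponent, seed = as.integer(seed))
}

# Noiseless voxel responses (voxels x trials) to a set of stimulus
# coordinates; null trials (NA coordinates) contribute nothing.
noiselessResponses <- function(voxels, xCoords, zCoords) {
  nTrials <- length(xCoords)
  nVox <- nrow(voxels@weights[[1]])
  out <- matrix(0, nVox, nTrials)
  coords <- list(x = xCoords, z = zCoords)
  for (ax in names(voxels@weights)) {
    cc <- voxels@centers[[ax]]
    s <- voxels@size[[ax]]
    co <- coords[[ax]]
    act <- matrix(0, length(cc), nTrials)    # channels x trials
    ok <- !is.na(co)
    if (any(ok))
      act[, ok] <- basisEval(abs(outer(cc, co[ok], "-")), s, voxels@exponent)
    out <- out + voxels@weights[[ax]] %*% act
  }
  out
}

#' Simulate trial-wise voxel responses
#'
#' Generates the trial response matrix for one run sequence: each stimulus
#' trial evokes the voxel's noiseless tuned response (generative channel
#' activations at the trial's coordinates times the voxel weights), plus
#' iid Gaussian noise of standard deviation `noiseSd`. Null trials produce
#' pure noise.
#'
#' @param voxels a [VoxelPopulation-class].
#' @param grid the [StimulusGrid-class] the trials are drawn from.
#' @param trialSequence data.frame with columns `row_index` and `col_index`
#'   (NA for null trials); one row per trial, in presentation order.
#' @param noiseSd trial noise standard deviation (response units).
#' @param seed integer seed for the noise.
#' @return voxels x trials response matrix with attribute `"info"`, the
#'   per-trial metadata (positions, scene coordinates, is_null).
#' @export
simulateTrialResponses <- function(voxels, grid, trialSequence, noiseSd = 0,
                                   seed = 1L) {
  loc <- gridLocations(grid)
  key <- paste(loc$row_index, loc$col_index)
  isNull <- is.na(trialSequence$row_index)
  tkey <- paste(trialSequence$row_index, trialSequence$col_index)
  hit <- match(tkey, key)
  if (any(is.na(hit) & !isNull))
    stop("trial position(s) not present in the grid: ",
      paste(unique(tkey[is.na(hit) & !isNull]), collapse = "; "))
  x <- ifelse(isNull, NA_real_, loc$x_scene[hit])
  z <- ifelse(isNull, NA_real_, loc$z_scene[hit])
  mu <- noiselessResponses(voxels, x, z)
  B <- if (noiseSd > 0) {
    mu + with_seed(as.integer(seed),
      matrix(rnorm(length(mu), sd = noiseSd), nrow(mu)))
  } else mu
  attr(B, "info") <- data.frame(
    row_index = trialSequence$row_index, col_index = trialSequence$col_index,
    x = x, z = z, is_null = isNull, mirrored = grid@mirrored)
  B
}

# shuffled run sequence: one trial per grid location plus nNull null trials
runTrialSequence <- function(nNull = 9L, seed = 1L) {
  base <- expand.grid(col_index = 1:6, row_index = 1:6)[, c("row_index", "col_index")]
  nulls <- data.frame(row_index = rep(NA_integer_, nNull),
    col_index = rep(NA_integer_, nNull))
  seq <- rbind(base, nulls)
  seq[with_seed(as.integer(seed), sample.int(nrow(seq))), , drop = FALSE]
}

#' Simulate a multi-subject experiment
#'
#' Generates the full synthetic study: independent voxel populations per
#' subject, and for each subject a set of runs with 36 stimulus trials (one
#' per grid location, shuffled order) plus `nNull` null trials. The grid is
#' horizontally mirrored on alternate runs (by default the even-numbered
#' ones) so that each run pair samples 72 distinct locations.
#'
#' The trial noise SD may be given in absolute response units
#' (`noise = list(type = "absolute", sd = ...)`) or relative to the signal
#' (`type = "relative"`, the default), where the SD is `sd` times the mean
#' over voxels of the peak noiseless response across grid locations.
#'
#' @param nSubjects number of subjects (default 9).
#' @param nRuns runs per subject (>= 2; default 26, i.e. 13 run pairs).
#' @param nVoxels voxels per subject.
#' @param noise list with `type` (`"relative"` or `"absolute"`) and `sd`.
#' @param nNull null trials per run.
#' @param mirrorRuns which runs use the mirrored grid (`"even"` or `"odd"`).
#' @param geom,spacing grid construction settings (see [makeGrid()]).
#' @param seed master seed; everything is reproducible from it.
#' @param ... passed to [makeVoxels()] (generative tuning settings).
#' @return a [SimulatedExperiment-class].
#' @examples
#' sim <- simulateExperiment(nSubjects = 2, nRuns = 4, nVoxels = 20, seed = 1)
#' sim
#' @export
simulateExperiment <- function(nSubjects = 9L, nRuns = 26L, nVoxels = 60L,
                               noise = list(type = "relative", sd = 2.5),
                               nNull = 9L, mirrorRuns = c("even", "odd"),
                               geom = ViewerGeometry(),
                               spacing = gridSpacing(geom),
                               seed = 1L, ...) {
  mirrorRuns <- match.arg(mirrorRuns)
  if (nRuns < 2L)
    stop("nRuns must be >= 2: leave-one-run-out cross-validation needs ",
      "at least two runs")
  gridBase <- makeGrid(geom, spacing, mirrored = FALSE)
  gridMirror <- makeGrid(geom, spacing, mirrored = TRUE)
  subjects <- vector("list", nSubjects)
  voxelSets <- vector("list", nSubjects)
  noiseSds <- numeric(nSubjects)
  for (s in seq_len(nSubjects)) {
    vox <- makeVoxels(nVoxels, seed = childSeed(seed, s, 0L), ...)
    noiseSds[s] <- resolveNoiseSd(noise, vox, gridBase, gridMirror)
    runs <- lapply(seq_len(nRuns), function(r) {
      mirrored <- if (mirrorRuns == "even") r %% 2L == 0L else r %% 2L == 1L
      g <- if (mirrored) gridMirror else gridBase
      tseq <- runTrialSequence(nNull, seed = childSeed(seed, s, r))
      B <- simulateTrialResponses(vox, g, tseq, noiseSd = noiseSds[s],
        seed = childSeed(seed, s, r, 1L))
      info <- attr(B, "info")
      info$run <- r
      list(B = B, info = info)
    })
    B <- do.call(cbind, lapply(runs, `[[`, "B"))
    info <- do.call(rbind, lapply(runs, `[[`, "info"))
    subjects[[s]] <- TrialExperiment(B, info)
    voxelSets[[s]] <- vox
  }
  new("SimulatedExperiment", subjects = subjects, voxels = voxelSets,
    gridBase = gridBase, gridMirror = gridMirror, noiseSd = noiseSds,
    seed = as.integer(seed),
    config = list(nSubjects = nSubjects, nRuns = nRuns, nVoxels = nVoxels,
      noise = noise, nNull = nNull, mirrorRuns = mirrorRuns))
}

# translate a noise spec into an absolute SD for one voxel population
resolveNoiseSd <- function(noise, voxels, gridBase, gridMirror) {
  type <- noise$type %||% "relative"
  sd <- noise$sd
  if (is.null(sd)) stop("noise$sd must be given")
  if (type == "absolute") return(sd)
  if (type != "relative") stop("unknown noise type: ", type)
  loc <- rbind(gridLocations(gridBase), gridLocations(gridMirror))
  mu <- noiselessResponses(voxels, loc$x_scene, loc$z_scene)
  peak <- mean(apply(mu, 1, max))
  sd * peak
}
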