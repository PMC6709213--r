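#' Canonical two-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a response peaking at `peak` seconds
#' minus an undershoot peaking at `undershootPeak` seconds and scaled down
#' by `ratio`. With the default dispersions of 1 s the gamma shapes are
#' `peak/dispersion + 1` and `undershootPeak/dispersion + 1`, which places
#' the modes exactly at 5 s and 15 s. `h(0) = 0`.
#'
#' @param t time(s) in seconds, `t >= 0`; vectorized.
#' @param peak response peak time, s.
#' @param undershootPeak undershoot peak time, s.
#' @param ratio response-to-undershoot amplitude ratio.
#' @param responseDispersion,undershootDispersion gamma dispersions, s.
#' @return unitless HRF amplitude at `t`.
#' @examples
#' tt <- seq(0, 30, 0.1)
#' tt[which.max(hrfDoubleGamma(tt))]   # 5
#' @export
hrfDoubleGamma <- function(t, peak = 5, undershootPeak = 15, ratio = 6,
                           responseDispersion = 1, undershootDispersion = 1) {
  if (any(t < 0)) stop("t must be >= 0")
  if (any(c(peak, undershootPeak, ratio, responseDispersion,
      undershootDispersion) <= 0))
    stop("all HRF parameters must be positive")
  dgamma(t, shape = peak / responseDispersion + 1,
      scale = responseDispersion) -
    dgamma(t, shape = undershootPeak / undershootDispersion + 1,
      scale = undershootDispersion) / ratio
}

#' Simulate an HRF-convolved voxel time series for one run
#'
#' Builds an event schedule (lead-in fixation, stimulus and null trials
#' with jittered inter-trial intervals, lead-out fixation), convolves each
#' stimulus trial's noiseless response with the HRF sampled at the volume
#' times, and adds a per-voxel linear drift and white noise. Trial onsets
#' are not locked to volume acquisitions. The default 300-s run at TR 2 s
#' yields 150 volumes.
#'
#' ITIs are drawn uniformly from `itiRange` and then rescaled by a common
#' factor so the schedule exactly fills the run; an explicit `events` table
#' that runs past the end of the run is an error.
#'
#' @param voxels a [VoxelPopulation-class].
#' @param grid a [StimulusGrid-class].
#' @param events optional data.frame (`onset_s`, `duration_s`, `row_index`,
#'   `col_index`) overriding the generated schedule; NA positions are null
#'   trials.
#' @param nTrials,nNull stimulus and null trials when generating a schedule.
#' @param TR repetition time, s.
#' @param runDuration run length, s (must be a multiple of TR).
#' @param stimDuration stimulus-on time per trial, s.
#' @param itiRange inter-trial-interval jitter range, s.
#' @param leadIn,leadOut passive fixation at run start and end, s.
#' @param noiseSd white-noise SD on each volume.
#' @param driftAmp peak-to-peak amplitude of a per-voxel linear drift.
#' @param hrfParams list of arguments for [hrfDoubleGamma()].
#' @param seed integer seed.
#' @return list with `series` (voxels x volumes matrix), `events` (the
#'   schedule with scene coordinates) and `TR`.
#' @export
simulateTimeseries <- function(voxels, grid, events = NULL,
                               nTrials = 36L, nNull = 9L, TR = 2,
                               runDuration = 300, stimDuration = 3,
                               itiRange = c(2, 6), leadIn = 2, leadOut = 10,
                               noiseSd = 0, driftAmp = 0,
                               hrfParams = list(), seed = 1L) {
  nVol <- as.integer(round(runDuration / TR))
  loc <- gridLocations(grid)
  if (is.null(events)) {
    events <- with_seed(as.integer(seed), {
      seqTab <- runTrialSequence(nNull, seed = childSeed(seed, 2L))
      seqTab <- seqTab[seq_len(min(nrow(seqTab), nTrials + nNull)), , drop = FALSE]
      iti <- runif(nrow(seqTab), itiRange[1], itiRange[2])
      avail <- runDuration - leadIn - leadOut - nrow(seqTab) * stimDuration
      if (avail <= 0) stop("run too short for the requested trial count")
      iti <- iti * (avail / sum(iti))
      onsets <- leadIn + cumsum(c(0, head(stimDuration + iti, -1)))
      data.frame(onset_s = onsets, duration_s = stimDuration,
        row_index = seqTab$row_index, col_index = seqTab$col_index)
    })
  }
  if (any(events$onset_s + events$duration_s > runDuration - 1e-9))
    stop("event schedule extends beyond the end of the run")
  isNull <- is.na(events$row_index)
  hit <- match(paste(events$row_index, events$col_index),
    paste(loc$row_index, loc$col_index))
  if (any(is.na(hit) & !isNull)) stop("event position(s) not in the grid")
  events$x <- ifelse(isNull, NA_real_, loc$x_scene[hit])
  events$z <- ifelse(isNull, NA_real_, loc$z_scene[hit])
  events$is_null <- isNull

  mu <- noiselessResponses(voxels, events$x, events$z)  # voxels x events
  volTimes <- (seq_len(nVol) - 1) * TR
  # each stimulus event contributes its response scaled by the HRF sampled
  # at (volume time - onset); boxcar of the stimulus duration convolved
  hrfAt <- function(lag) {
    v <- numeric(length(lag))
    ok <- lag >= 0
    if (any(ok)) {
      ts <- seq(0, stimDuration, by = min(0.1, stimDuration))
      v[ok] <- rowMeans(matrix(vapply(ts, function(dt)
        do.call(hrfDoubleGamma, c(list(t = pmax(lag[ok] - dt, 0)), hrfParams)),
        numeric(sum(ok))), nrow = sum(ok)))
    }
    v
  }
  H <- vapply(events$onset_s, function(on) hrfAt(volTimes - on),
    numeric(nVol))                                      # volumes x events
  series <- mu %*% t(H)
  series <- series + with_seed(childSeed(seed, 3L), {
    noise <- if (noiseSd > 0)
      matrix(rnorm(length(series), sd = noiseSd), nrow(series))
    else 0
    drift <- if (driftAmp > 0)
      outer(runif(nrow(series), -driftAmp / 2, driftAmp / 2),
        seq(-1, 1, length.out = nVol))
    else 0
    noise + drift
  })
  list(series = series, events = events, TR = TR)
}

#' Extract trial-wise activation estimates from a run time series
#'
#' Mirrors the standard single-trial estimate: z-score each voxel's series
#' within the run, then average the volumes at offsets +3 and +4 from the
#' trial's reference volume (the last volume acquired at or before stimulus
#' onset), i.e. roughly 6-8 s post-onset where the HRF peaks.
#'
#' @param run a list with `series`, `events`, `TR` as returned by
#'   [simulateTimeseries()].
#' @param offsets volume offsets averaged for the estimate.
#' @param onIncomplete what to do with trials whose extraction volumes run
#'   past the end of the series: `"error"` or `"drop"` (with a warning).
#' @return voxels x trials matrix with attribute `"info"` as in
#'   [simulateTrialResponses()].
#' @export
extractTrialEstimates <- function(run, offsets = c(3L, 4L),
                                  onIncomplete = c("error", "drop")) {
  onIncomplete <- match.arg(onIncomplete)
  series <- run$series
  events <- run$events
  TR <- run$TR
  sds <- apply(series, 1, sd)
  if (any(sds == 0))
    stop("constant voxel time series cannot be z-scored")
  zs <- (series - rowMeans(series)) / sds
  refVol <- floor(events$onset_s / TR) + 1L
  need <- refVol + max(offsets)
  bad <- need > ncol(series)
  if (any(bad)) {
    if (onIncomplete == "error")
      stop(sum(bad), " trial(s) too close to the end of the run")
    warning("dropping ", sum(bad), " trial(s) too close to the end of the run")
    events <- events[!bad, , drop = FALSE]
    refVol <- refVol[!bad]
  }
  est <- vapply(refVol, function(v) rowMeans(zs[, v + offsets, drop = FALSE]),
    numeric(nrow(zs)))
  est <- matrix(est, nrow = nrow(zs))
  attr(est, "info") <- data.frame(
    row_index = events$row_index, col_index = events$col_index,
    x = events$x, z = events$z, is_null = events$is_null)
  est
}
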