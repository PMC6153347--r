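#' Normalize voxel time series
#'
#' Z-scores every in-mask voxel over the time dimension, separately per run
#' (runs were acquired separately; per-run scaling keeps run-level offsets
#' out of the decoder). A voxel with zero temporal variance in a run is set
#' to all-zero for that run, with a warning naming how many voxels were
#' affected. Idempotent up to floating point.
#'
#' @param subject a [SubjectData-class].
#' @return the subject with normalized `bold` (out-of-mask voxels untouched).
#' @export
normalizeVoxels <- function(subject) {
  stopifnot(is(subject, "SubjectData"))
  maskIdx <- which(subject@mask)
  grid <- dim(subject@bold)[1:3]
  nT <- dim(subject@bold)[4L]
  flat <- matrix(subject@bold, prod(grid), nT)    # voxels x time
  t0 <- 0L
  nZero <- 0L
  for (len in subject@runLengths) {
    cols <- t0 + seq_len(len)
    x <- flat[maskIdx, cols, drop = FALSE]
    mu <- rowMeans(x)
    s <- sqrt(rowSums((x - mu)^2) / (len - 1L))
    zero <- s == 0
    nZero <- nZero + sum(zero)
    s[zero] <- Inf                                # (x - mu) is 0 there anyway
    flat[maskIdx, cols] <- (x - mu) / s
    t0 <- t0 + len
  }
  if (nZero > 0)
    warning(nZero, " zero-variance voxel-run(s) set to all-zero")
  subject@bold <- array(flat, dim = c(grid, nT))
  subject
}

#' Extract raw trial windows
#'
#' For every trial, pulls the nine TR samples at 0, 2, ..., 16 s after
#' sentence onset for every in-mask voxel — the span a 3-point moving
#' average needs to produce the seven analysis windows centred 2--14 s.
#' Onsets not aligned to the TR grid are rounded to the nearest TR with a
#' warning.
#'
#' @param subject a (normalized) [SubjectData-class].
#' @return list with `raw` (trials x voxels x 9 array), `voxelIndex`
#'   (linear grid indices of the voxel columns) and `sampleTimes`
#'   (0, 2, ..., 16 s).
#' @export
extractTrialWindows <- function(subject) {
  stopifnot(is(subject, "SubjectData"))
  tr <- subject@tr
  trials <- subject@trials
  maskIdx <- which(subject@mask)
  grid <- dim(subject@bold)[1:3]
  nT <- dim(subject@bold)[4L]
  flat <- matrix(subject@bold, prod(grid), nT)[maskIdx, , drop = FALSE]
  runStart <- cumsum(c(0L, subject@runLengths))
  sampleTimes <- seq(0, 16, by = tr)
  nS <- length(sampleTimes)
  out <- array(NA_real_, dim = c(nrow(trials), length(maskIdx), nS))
  misaligned <- 0L
  for (i in seq_len(nrow(trials))) {
    run <- trials$run[i]
    onTR <- trials$onset[i] / tr
    if (abs(onTR - round(onTR)) > 1e-8) misaligned <- misaligned + 1L
    onTR <- round(onTR)
    rows <- onTR + seq_len(nS)                    # run-relative TR indices
    if (max(rows) > subject@runLengths[run])
      stop(sprintf(
        "trial %d (run %d, onset %.1f s): 0-16 s window exceeds run bounds",
        i, run, trials$onset[i]))
    out[i, , ] <- flat[, runStart[run] + rows, drop = FALSE]
  }
  if (misaligned > 0)
    warning(misaligned, " onset(s) not aligned to the TR grid; ",
            "rounded to the nearest TR")
  list(raw = out, voxelIndex = maskIdx, sampleTimes = sampleTimes)
}

#' Temporal smoothing into seven overlapping windows
#'
#' Central 3-point moving average over the nine trial-locked samples:
#' window k (centre 2k s post-onset, k = 1..7) is the mean of the samples at
#' 2k - 2, 2k and 2k + 2 s. Linear and shift-equivariant.
#'
#' @param raw trials x voxels x 9 array (samples at 0--16 s, 2 s apart).
#' @return trials x voxels x 7 array of smoothed window values.
#' @export
temporalSmooth <- function(raw) {
  d <- dim(raw)
  if (length(d) != 3L || d[3L] != 9L)
    stop("raw must be a trials x voxels x 9 array")
  (raw[, , 1:7, drop = FALSE] + raw[, , 2:8, drop = FALSE] +
     raw[, , 3:9, drop = FALSE]) / 3
}

#' Build the trial-window tensor for one subject
#'
#' Convenience composition of [normalizeVoxels()], [extractTrialWindows()]
#' and [temporalSmooth()] producing the decoder's input.
#'
#' @param subject a [SubjectData-class] (raw; normalization is applied here).
#' @param normalize set `FALSE` if `subject` is already normalized.
#' @return a [TrialTensor-class].
#' @export
buildTrialTensor <- function(subject, normalize = TRUE) {
  if (normalize) subject <- normalizeVoxels(subject)
  ex <- extractTrialWindows(subject)
  vals <- temporalSmooth(ex$raw)
  new("TrialTensor", values = vals, windowTimes = WINDOW_TIMES,
      voxelIndex = as.integer(ex$voxelIndex),
      gridDim = dim(subject@bold)[1:3],
      trials = subject@trials)
}
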