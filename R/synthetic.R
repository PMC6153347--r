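#' Construct a cohort specification
#'
#' Builds a validated [CohortSpec-class]. Defaults emulate the target study
#' design: 14 subjects split 8 (wedding) / 6 (funeral), 48 trials per subject
#' (24 true, 24 false) over 3 runs, TR 2 s, a 20x20x20 voxel grid with a
#' ball-shaped gray-matter mask, and 2,000 informative voxels planted as
#' contiguous blobs. The planted effect appears at a per-subject latency
#' drawn from the seven analysis windows (2--14 s).
#'
#' @param nSubjects,groupSizes,nTrials,nRuns,tr see [CohortSpec-class].
#' @param gridShape,maskFraction,nInformative grid geometry.
#' @param latency `numeric(0)` to draw a latency per subject, or a scalar
#'   in \{2, 4, ..., 14\} to fix it.
#' @param effectSize standardized true-minus-false amplitude difference.
#' @param trialSd trial-to-trial shared amplitude variability (window-scale
#'   SD); see [CohortSpec-class].
#' @param noiseAr1 lag-1 noise autocorrelation.
#' @param trialSpacing onset spacing in seconds (>= 18).
#' @param seed master seed.
#' @return a [CohortSpec-class] object.
#' @examples
#' spec <- cohortSpec(seed = 1)
#' spec
#' @export
cohortSpec <- function(nSubjects = 14L, groupSizes = c(8L, 6L),
                       nTrials = 48L, nRuns = 3L, tr = 2,
                       gridShape = c(20L, 20L, 20L), maskFraction = 0.7,
                       nInformative = 2000L, latency = numeric(0),
                       effectSize = 2, trialSd = 1, noiseAr1 = 0.3,
                       trialSpacing = 18, seed = 1L) {
  new("CohortSpec",
      nSubjects = as.integer(nSubjects),
      groupSizes = as.integer(groupSizes),
      nTrials = as.integer(nTrials),
      nRuns = as.integer(nRuns),
      tr = as.numeric(tr),
      gridShape = as.integer(gridShape),
      maskFraction = as.numeric(maskFraction),
      nInformative = as.integer(nInformative),
      latency = as.numeric(latency),
      effectSize = as.numeric(effectSize),
      trialSd = as.numeric(trialSd),
      noiseAr1 = as.numeric(noiseAr1),
      trialSpacing = as.numeric(trialSpacing),
      seed = as.integer(seed))
}

## Deterministic ball mask: the maskFraction * prod(grid) voxels closest to
## the grid centre (anisotropy-scaled so the ball fills the grid evenly).
.makeMask <- function(gridShape, maskFraction) {
  n <- prod(gridShape)
  keep <- round(maskFraction * n)
  coord <- arrayInd(seq_len(n), gridShape)
  ctr <- (gridShape + 1) / 2
  d2 <- ((coord[, 1L] - ctr[1L]) / gridShape[1L])^2 +
        ((coord[, 2L] - ctr[2L]) / gridShape[2L])^2 +
        ((coord[, 3L] - ctr[3L]) / gridShape[3L])^2
  sel <- order(d2)[seq_len(keep)]
  m <- array(FALSE, dim = gridShape)
  m[sel] <- TRUE
  m
}

## Plant nInformative voxels as a few contiguous blobs (each >= 21 voxels)
## inside the mask: blob seeds are drawn from the mask, then each blob takes
## the nearest still-free mask voxels around its seed.
.makeInfoMask <- function(mask, nInformative, gridShape) {
  maskIdx <- which(mask)
  if (nInformative > length(maskIdx))
    stop("grid too small: mask holds ", length(maskIdx),
         " voxels but ", nInformative, " informative voxels requested")
  nBlobs <- max(1L, min(round(nInformative / 400), nInformative %/% 21L))
  sizes <- rep(nInformative %/% nBlobs, nBlobs)
  extra <- nInformative - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  coord <- arrayInd(maskIdx, gridShape)
  free <- rep(TRUE, length(maskIdx))
  seeds <- sample(length(maskIdx), nBlobs)
  out <- integer(0)
  for (b in seq_len(nBlobs)) {
    s <- coord[seeds[b], ]
    d2 <- (coord[, 1L] - s[1L])^2 + (coord[, 2L] - s[2L])^2 +
          (coord[, 3L] - s[3L])^2
    d2[!free] <- Inf
    take <- order(d2)[seq_len(sizes[b])]
    free[take] <- FALSE
    out <- c(out, maskIdx[take])
  }
  m <- array(FALSE, dim = gridShape)
  m[out] <- TRUE
  m
}

## Raw 9-TR amplitude profile whose 3-point moving average equals 1 at
## window `winIdx` (1..7) and 0 at the other six windows: minimum-norm
## solution of the underdetermined smoothing system (7 equations, 9 TRs).
.windowConfinedProfile <- function(winIdx) {
  A <- matrix(0, 7, 9)
  for (j in 1:7) A[j, j:(j + 2L)] <- 1 / 3
  target <- replace(numeric(7), winIdx, 1)
  drop(crossprod(A, solve(tcrossprod(A), target)))
}

## AR(1) noise, stationary unit variance, independent across voxels/runs.
.ar1Noise <- function(nTime, nVox, phi) {
  x <- matrix(0, nTime, nVox)
  x[1L, ] <- rnorm(nVox)
  if (nTime > 1L) {
    innov <- sqrt(1 - phi^2)
    for (t in 2:nTime) x[t, ] <- phi * x[t - 1L, ] + innov * rnorm(nVox)
  }
  x
}

## Balanced, shuffled trial labels for one subject (per-run balance when the
## per-run trial count is even).
.trialLabels <- function(nTrials, nRuns) {
  perRun <- nTrials %/% nRuns
  rem <- nTrials - perRun * nRuns
  counts <- rep(perRun, nRuns) + c(rep(1L, rem), rep(0L, nRuns - rem))
  labs <- unlist(lapply(counts, function(k) {
    if (k %% 2L == 0L) sample(rep(c("true", "false"), k / 2L))
    else sample(c(rep(c("true", "false"), k %/% 2L),
                  sample(c("true", "false"), 1L)))
  }))
  ## enforce the global balance exactly (swap surplus labels if per-run
  ## counts were odd)
  surplus <- sum(labs == "true") - nTrials / 2L
  while (surplus != 0) {
    from <- if (surplus > 0) "true" else "false"
    to <- if (surplus > 0) "false" else "true"
    cand <- which(labs == from)
    labs[cand[sample.int(length(cand), 1L)]] <- to
    surplus <- sum(labs == "true") - nTrials / 2L
  }
  list(labels = labs, counts = counts)
}

#' Generate one synthetic subject
#'
#' Simulates a single subject of a [CohortSpec-class] cohort. The voxel
#' time series is AR(1) Gaussian noise (unit stationary variance), plus two
#' trial-locked components confined to the informative voxels:
#' \itemize{
#'   \item the condition response: a 9-TR amplitude profile over the
#'     0--16 s trial window, solved (minimum-norm) so that the 3-point
#'     temporal smoothing maps it to exactly +/- effectSize/2 at the
#'     window centred on the subject's latency and exactly zero at the six
#'     other windows — the planted effect is confined to one analysis
#'     window, with a true-minus-false difference of `effectSize` noise
#'     standard deviations there;
#'   \item a trial-level amplitude fluctuation shared across informative
#'     voxels (independent across TRs, window-scale SD `trialSd`), which
#'     bounds single-trial decoding away from 100% the way real
#'     trial-by-trial variability does.
#' }
#' The informative blobs are drawn once per cohort (from `spec@seed`), so
#' every subject shares the same informative regions while latency, labels
#' and noise vary per subject — the premise the group-level sparseness test
#' probes. The signal is generated directly as trial-locked normalized
#' response — the data stand in for residualized, registered time series,
#' so no hemodynamic convolution is applied.
#'
#' Deterministic given `(spec@seed, subjectIndex)`; the caller's RNG state is
#' left untouched.
#'
#' @param spec a [CohortSpec-class].
#' @param subjectIndex 1-based subject index (`<= nSubjects`).
#' @return a [SubjectData-class] object. The ground-truth informative mask
#'   and latency are carried along for validation only.
#' @examples
#' sd1 <- generateSubject(cohortSpec(gridShape = c(8, 8, 8),
#'                                   nInformative = 40, nTrials = 8,
#'                                   seed = 7), 1)
#' sd1
#' @export
generateSubject <- function(spec, subjectIndex) {
  stopifnot(is(spec, "CohortSpec"))
  validObject(spec)
  subjectIndex <- as.integer(subjectIndex)
  if (subjectIndex < 1L || subjectIndex > spec@nSubjects)
    stop("subjectIndex out of range")
  grid <- spec@gridShape
  mask <- .makeMask(grid, spec@maskFraction)
  ## informative blobs are a cohort-level property: drawn from the spec
  ## seed, identical for every subject
  infoMask <- .withSeed(.substreamSeed(spec@seed, "simulate", 0L),
                        .makeInfoMask(mask, spec@nInformative, grid))
  seed <- .substreamSeed(spec@seed, "simulate", subjectIndex)
  .withSeed(seed, {
    latency <- if (length(spec@latency)) spec@latency
               else sample(WINDOW_TIMES, 1L)

    tl <- .trialLabels(spec@nTrials, spec@nRuns)
    leadIn <- 4                       # s before the first onset
    tail <- 18                        # s after the last onset (window + slack)
    runLenTR <- integer(spec@nRuns)
    onsets <- numeric(0); runs <- integer(0)
    for (r in seq_len(spec@nRuns)) {
      k <- tl$counts[r]
      on <- leadIn + spec@trialSpacing * (seq_len(k) - 1L)
      onsets <- c(onsets, on)
      runs <- c(runs, rep(r, k))
      runLenTR[r] <- as.integer(ceiling((max(on) + tail) / spec@tr))
    }
    trials <- data.frame(onset = onsets, duration = 5.5, run = runs,
                         trial_type = tl$labels,
                         stringsAsFactors = FALSE)

    nVox <- prod(grid)
    totalTR <- sum(runLenTR)
    bold <- matrix(0, totalTR, nVox)
    t0 <- 0L
    for (r in seq_len(spec@nRuns)) {
      bold[t0 + seq_len(runLenTR[r]), ] <-
        .ar1Noise(runLenTR[r], nVox, spec@noiseAr1)
      t0 <- t0 + runLenTR[r]
    }

    ## Trial-locked components in the informative voxels. The condition
    ## amplitude follows the window-confined 9-TR profile, so after the
    ## 3-point smoothing the planted effect is +/- effectSize/2 at the
    ## latency window and exactly zero at the other six. The shared
    ## trial-level fluctuation is injected at every TR of the 0-16 s trial
    ## window with per-TR SD trialSd*sqrt(3), giving each smoothed window
    ## a fluctuation SD of trialSd.
    infoIdx <- which(infoMask)
    runStart <- cumsum(c(0L, runLenTR[-spec@nRuns]))
    profile <- .windowConfinedProfile(match(latency, WINDOW_TIMES))
    winTimes <- seq(0, 16, by = 2)
    for (i in seq_len(nrow(trials))) {
      amp <- if (trials$trial_type[i] == "true") spec@effectSize / 2
             else -spec@effectSize / 2
      tr0 <- runStart[trials$run[i]] + round(trials$onset[i] / spec@tr) + 1L
      rows <- tr0 + round(winTimes / spec@tr)
      jit <- rnorm(length(rows), sd = spec@trialSd * sqrt(3))
      bold[rows, infoIdx] <- bold[rows, infoIdx] + (amp * profile + jit)
    }

    new("SubjectData",
        bold = array(t(bold), dim = c(grid, totalTR)),
        mask = mask, trials = trials, runLengths = runLenTR,
        group = "wedding", infoMask = infoMask, latency = latency,
        tr = spec@tr, subject = sprintf("sub-%02d", subjectIndex))
  })
}

#' Generate a full synthetic cohort
#'
#' Calls [generateSubject()] for every subject of the spec. The first
#' `groupSizes[1]` subjects are labelled "wedding", the remainder "funeral".
#' Per-subject seeds derive deterministically from `spec@seed`, so two
#' cohorts built from the same spec are identical.
#'
#' @param spec a [CohortSpec-class].
#' @return list of [SubjectData-class] objects, length `nSubjects`.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  groups <- rep(c("wedding", "funeral"), spec@groupSizes)
  lapply(seq_len(spec@nSubjects), function(i) {
    sd <- generateSubject(spec, i)
    sd@group <- groups[i]
    sd
  })
}
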