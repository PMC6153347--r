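## Permutation-based significance for the single-subject decoding.
##
## The null is empirical — built from the subject's own data by shuffling
## the behavioral (true/false) vector — because the chance level of the
## matching procedure need not sit at 50% and the effective degrees of
## freedom are unknown. Two details make the null exactly exchangeable
## with the observed statistic:
##   * one shuffled vector is drawn per replicate and the COMPLETE decoding
##     procedure (fold enumeration, training, voxel selection, pattern
##     matching) is re-run under it, so every replicate is the same
##     functional of the data as the observed accuracy;
##   * labels are shuffled within runs. Per-run normalization makes trials
##     within a run jointly standardized (they share the estimated run mean
##     and SD), so within-run relabelling is the transformation that leaves
##     the data distribution invariant under the no-signal hypothesis.

## Within-run label shuffle (preserves per-run class counts).
.shuffleWithinRuns <- function(labels, runs) {
  out <- labels
  for (r in unique(runs)) {
    i <- which(runs == r)
    out[i] <- labels[i][sample.int(length(i))]
  }
  out
}

#' Decoding accuracy under one label permutation
#'
#' Re-runs the complete leave-two-out decoding at one window with the
#' behavioral (true/false) vector replaced by a permuted copy: folds are
#' enumerated from the permuted labels, the encoding model is trained on
#' them, and the two left-out patterns are matched against the conditions
#' the permuted vector assigns. One permutation is drawn per replicate and
#' reused across all folds (shuffle-then-decode), preserving the
#' dependence structure among folds that the observed accuracy has.
#'
#' @param tensor a [TrialTensor-class].
#' @param window window centre in seconds.
#' @param permLabels optional explicit permuted label vector; if `NULL`,
#'   one is drawn from the current RNG state by shuffling within runs.
#' @param nTop,minCluster,connectivity see [selectVoxels()].
#' @return the permuted-label accuracy (scalar).
#' @export
permutedAccuracy <- function(tensor, window, permLabels = NULL,
                             nTop = 2000L, minCluster = 21L,
                             connectivity = 6L) {
  stopifnot(is(tensor, "TrialTensor"))
  w <- match(window, tensor@windowTimes)
  if (is.na(w)) stop("unknown window: ", window)
  labels <- tensor@trials$trial_type
  if (is.null(permLabels))
    permLabels <- .shuffleWithinRuns(labels, tensor@trials$run)
  if (!identical(sort(as.character(permLabels)), sort(as.character(labels))))
    stop("permLabels must be a permutation of the trial labels")
  Y <- tensor@values[, , w]
  folds <- enumerateFolds(permLabels)
  xPerm <- ifelse(.isTrueLabel(permLabels), 1, -1)
  mean(.decodeCore(Y, xPerm, folds, tensor@voxelIndex, tensor@gridDim,
                   nTop, minCluster, connectivity))
}

#' Build the empirical null distribution
#'
#' Draws `nPerWindow` permutation replicates per window (independent draws
#' per window) and pools them: the default 100 x 7 gives the 700-value
#' common reference distribution against which every window's observed
#' accuracy is tested.
#'
#' @param tensor a [TrialTensor-class].
#' @param nPerWindow permutation replicates per window.
#' @param seed RNG seed for the permutation substream.
#' @param nTop,minCluster,connectivity see [selectVoxels()].
#' @return a [NullDistribution-class].
#' @export
buildNull <- function(tensor, nPerWindow = 100L, seed = 1L,
                      nTop = 2000L, minCluster = 21L, connectivity = 6L) {
  stopifnot(is(tensor, "TrialTensor"))
  vals <- .withSeed(.substreamSeed(seed, "null"), {
    vapply(seq_along(WINDOW_TIMES), function(w) {
      vapply(seq_len(nPerWindow), function(r)
        permutedAccuracy(tensor, WINDOW_TIMES[w],
                         nTop = nTop, minCluster = minCluster,
                         connectivity = connectivity),
        numeric(1))
    }, numeric(nPerWindow))
  })
  vals <- matrix(vals, nrow = nPerWindow)
  new("NullDistribution", values = vals, windowTimes = WINDOW_TIMES,
      seed = as.integer(seed))
}

#' One-sided permutation rank test
#'
#' Add-one rank test of an observed accuracy against the pooled null:
#' `p = (1 + #\{null >= observed\}) / (1 + N)`. The p-value can never be
#' zero; significance is conventionally declared at p < 0.05.
#'
#' @param observed observed accuracy (scalar or vector).
#' @param null a [NullDistribution-class] or numeric vector of null values.
#' @return p-value(s), same length as `observed`.
#' @export
rankTest <- function(observed, null) {
  nv <- if (is(null, "NullDistribution")) nullValues(null) else as.numeric(null)
  if (length(nv) == 0L) stop("null distribution is empty")
  vapply(observed, function(a) (1 + sum(nv >= a)) / (1 + length(nv)),
         numeric(1))
}

#' Attach permutation p-values to a decoding result
#'
#' Tests every window's observed accuracy against the pooled null with
#' [rankTest()].
#'
#' @param result a [DecodingResult-class].
#' @param null a [NullDistribution-class].
#' @return the result with `pValues` filled in.
#' @export
applyRankTest <- function(result, null) {
  stopifnot(is(result, "DecodingResult"))
  result@pValues <- rankTest(result@accuracy, null)
  result
}
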