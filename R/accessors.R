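#' @describeIn accessors per-window decoding accuracies (named by window
#'   centre in seconds).
#' @export
setMethod("accuracy", "DecodingResult", function(object, ...) {
  setNames(object@accuracy, WINDOW_TIMES)
})

#' @describeIn accessors bootstrap standard errors of the accuracies.
#' @export
setMethod("accuracySE", "DecodingResult", function(object, ...) {
  setNames(object@se, WINDOW_TIMES)
})

#' @describeIn accessors window (seconds) with the highest accuracy,
#'   earliest on ties.
#' @export
setMethod("bestWindow", "DecodingResult", function(object, ...) object@bestWindow)

#' @describeIn accessors one-sided permutation p-values per window (NA until
#'   [applyRankTest()] is called).
#' @export
setMethod("pValues", "DecodingResult", function(object, ...) {
  setNames(object@pValues, WINDOW_TIMES)
})

#' @describeIn accessors decoding map for one window as a logical 3D array.
#' @param window window centre in seconds (default: the best window).
#' @export
setMethod("decodingMap", "DecodingResult", function(object, window = NULL, ...) {
  if (is.null(window)) window <- object@bestWindow
  w <- match(window, WINDOW_TIMES)
  if (is.na(w)) stop("window must be one of ", paste(WINDOW_TIMES, collapse = ", "))
  .logicalMap(object@maps[[w]], object@gridDim)
})

#' @describeIn accessors pooled null accuracies (all windows concatenated).
#' @export
setMethod("nullValues", "NullDistribution", function(object, ...) {
  as.vector(object@values)
})

#' @describeIn accessors the probability grid of a [ProbabilityMap-class].
#' @export
setMethod("probMap", "ProbabilityMap", function(object, ...) object@prob)

#' @describeIn accessors linear indices of the retained voxels.
#' @export
setMethod("selectedVoxels", "VoxelSelection", function(object, ...) object@selected)

#' @describeIn accessors trial table of a subject or tensor.
#' @export
setMethod("trialTable", "SubjectData", function(object, ...) object@trials)

#' @rdname accessors
#' @export
setMethod("trialTable", "TrialTensor", function(object, ...) object@trials)

#' @describeIn accessors window centres in seconds post-onset.
#' @export
setMethod("windowTimes", "TrialTensor", function(object, ...) object@windowTimes)

#' @describeIn accessors valence group label of a subject.
#' @export
setMethod("valenceGroup", "SubjectData", function(object, ...) object@group)

#' @describeIn accessors subject-by-subject Sorensen-Dice matrix.
#' @export
setMethod("diceMatrix", "GroupComparison", function(object, ...) object@diceMatrix)

setMethod("show", "CohortSpec", function(object) {
  cat("CohortSpec:", object@nSubjects, "subjects (",
      object@groupSizes[1L], "wedding /", object@groupSizes[2L], "funeral )\n")
  cat("  trials:", object@nTrials, "over", object@nRuns, "runs, TR",
      object@tr, "s, spacing", object@trialSpacing, "s\n")
  cat("  grid:", paste(object@gridShape, collapse = "x"),
      "| mask fraction", object@maskFraction,
      "| informative voxels:", object@nInformative, "\n")
  cat("  effect size:", object@effectSize,
      "| latency:", if (length(object@latency)) paste0(object@latency, " s")
      else "per-subject (2-14 s)",
      "| AR(1):", object@noiseAr1, "| seed:", object@seed, "\n")
})

setMethod("show", "SubjectData", function(object) {
  d <- dim(object@bold)
  cat("SubjectData", object@subject, "(", object@group, ")\n")
  cat("  grid", paste(d[1:3], collapse = "x"), "|", d[4L], "TRs in",
      length(object@runLengths), "runs |", sum(object@mask), "mask voxels\n")
  cat("  trials:", nrow(object@trials), "(",
      sum(object@trials$trial_type == "true"), "true ) | planted latency",
      object@latency, "s\n")
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@values)
  cat("TrialTensor:", d[1L], "trials x", d[2L], "voxels x", d[3L],
      "windows (", paste(range(object@windowTimes), collapse = "-"),
      "s post-onset )\n")
})

setMethod("show", "DecodingResult", function(object) {
  cat("DecodingResult", object@subject, "—", nrow(object@foldOutcomes),
      "leave-two-out folds\n")
  tab <- rbind(accuracy = round(object@accuracy, 3),
               se = round(object@se, 3),
               p = signif(object@pValues, 3))
  colnames(tab) <- paste0(WINDOW_TIMES, "s")
  print(tab)
  cat("best window:", object@bestWindow, "s\n")
})

setMethod("show", "NullDistribution", function(object) {
  cat("NullDistribution:", length(object@values), "accuracies (",
      nrow(object@values), "per window x", ncol(object@values), "windows )\n")
  cat("  mean", round(mean(object@values), 3),
      "| 95th percentile", round(quantile(object@values, 0.95), 3), "\n")
})

setMethod("show", "ProbabilityMap", function(object) {
  cat("ProbabilityMap over", object@nSubjects, "subjects;",
      sum(object@prob > 0), "voxels with non-zero probability; max",
      round(max(object@prob), 3), "\n")
})

setMethod("show", "GroupComparison", function(object) {
  cat("GroupComparison (wedding vs funeral)\n")
  cat("  best-window Mann-Whitney U =", object@uStat,
      ", two-tailed p =", signif(object@uP, 3), "\n")
  cat("  Dice ratio R =", round(object@R, 3), " 95% CI [",
      round(object@ci[1L], 3), ",", round(object@ci[2L], 3), "] (",
      object@nPerm, "permutations )\n")
  cat("  decision:", object@decision, "\n")
})

setMethod("show", "VoxelSelection", function(object) {
  cat("VoxelSelection:", length(object@selected), "voxels in",
      nrow(object@clusters), "clusters\n")
})

setMethod("show", "EncodingModel", function(object) {
  cat("EncodingModel over", length(object@weights), "voxels; max R^2 =",
      round(max(object@r2), 3), "\n")
})
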