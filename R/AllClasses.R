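#' Cohort specification for the synthetic-data generator
#'
#' Describes a simulated study cohort: how many subjects in each valence
#' group, the trial design, the voxel grid, and the planted true-versus-false
#' effect. Defaults reproduce the study design the pipeline targets:
#' 14 subjects (8 wedding, 6 funeral), 48 trials (24 true, 24 false) over
#' 3 runs at TR = 2 s, with 2,000 spatially clustered informative voxels.
#'
#' @slot nSubjects number of subjects.
#' @slot groupSizes integer(2): subjects in the wedding and funeral group.
#' @slot nTrials trials per subject (half labelled true, half false).
#' @slot nRuns runs per subject; trials are split evenly across runs.
#' @slot tr repetition time in seconds.
#' @slot gridShape integer(3) voxel grid dimensions.
#' @slot maskFraction fraction of grid voxels inside the gray-matter mask
#'   (a centred ball).
#' @slot nInformative number of informative voxels, planted as a few
#'   contiguous blobs inside the mask.
#' @slot latency informative latency in seconds. `numeric(0)` (default)
#'   draws one latency per subject uniformly from \{2, 4, ..., 14\};
#'   a scalar fixes it for every subject.
#' @slot effectSize standardized mean difference (true minus false) of the
#'   planted response amplitude in informative voxels, in units of the
#'   noise standard deviation.
#' @slot trialSd standard deviation (at the window scale) of the
#'   trial-to-trial response-amplitude fluctuation shared across
#'   informative voxels. This is what keeps single-trial decoding away
#'   from the ceiling: with many informative voxels the independent voxel
#'   noise averages out of the pattern match, and the trial-level
#'   fluctuation sets the attainable accuracy.
#' @slot noiseAr1 lag-1 autocorrelation of the AR(1) voxel noise.
#' @slot trialSpacing seconds between consecutive trial onsets within a run
#'   (must be >= 18 so 0--16 s extraction windows never overlap).
#' @slot seed master RNG seed; all per-subject seeds derive from it.
#' @seealso [cohortSpec()], [generateSubject()], [generateCohort()]
#' @export
setClass("CohortSpec", representation(
  nSubjects = "integer",
  groupSizes = "integer",
  nTrials = "integer",
  nRuns = "integer",
  tr = "numeric",
  gridShape = "integer",
  maskFraction = "numeric",
  nInformative = "integer",
  latency = "numeric",
  effectSize = "numeric",
  trialSd = "numeric",
  noiseAr1 = "numeric",
  trialSpacing = "numeric",
  seed = "integer"
))

setValidity("CohortSpec", function(object) {
  msg <- character(0)
  if (sum(object@groupSizes) != object@nSubjects)
    msg <- c(msg, "groupSizes must sum to nSubjects")
  if (length(object@groupSizes) != 2L)
    msg <- c(msg, "groupSizes must have length 2 (wedding, funeral)")
  if (object@nTrials %% 2L != 0L)
    msg <- c(msg, "nTrials must be even (balanced true/false)")
  if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
    msg <- c(msg, "gridShape must be three positive integers")
  if (object@maskFraction <= 0 || object@maskFraction > 1)
    msg <- c(msg, "maskFraction must be in (0, 1]")
  if (length(object@latency) > 1L ||
      (length(object@latency) == 1L && !(object@latency %in% WINDOW_TIMES)))
    msg <- c(msg, "latency must be numeric(0) or one of 2,4,...,14")
  if (abs(object@noiseAr1) >= 1)
    msg <- c(msg, "noiseAr1 must lie in (-1, 1)")
  if (object@trialSd < 0)
    msg <- c(msg, "trialSd must be non-negative")
  if (object@trialSpacing < 18)
    msg <- c(msg, "trialSpacing must be >= 18 s (non-overlapping windows)")
  if (length(msg)) msg else TRUE
})

#' Single-subject synthetic dataset
#'
#' A simulated subject: the 4D voxel time series (runs concatenated along the
#' fourth dimension), the gray-matter mask, the trial table, and — because the
#' data are synthetic — the ground-truth informative mask and latency, kept
#' for validation only and never consulted by the analysis.
#'
#' @slot bold 4D numeric array (x, y, z, TR index), runs concatenated.
#' @slot mask 3D logical array, the gray-matter mask.
#' @slot trials data.frame with columns `onset` (s from run start),
#'   `duration` (s), `run` (1-based), `trial_type` ("true"/"false").
#' @slot runLengths integer, TRs per run (sums to `dim(bold)[4]`).
#' @slot group valence group label, "wedding" or "funeral".
#' @slot infoMask 3D logical array, ground-truth informative voxels.
#' @slot latency seconds: the window at which the planted effect peaks.
#' @slot tr repetition time in seconds.
#' @slot subject subject identifier.
#' @export
setClass("SubjectData", representation(
  bold = "array",
  mask = "array",
  trials = "data.frame",
  runLengths = "integer",
  group = "character",
  infoMask = "array",
  latency = "numeric",
  tr = "numeric",
  subject = "character"
))

setValidity("SubjectData", function(object) {
  msg <- character(0)
  if (length(dim(object@bold)) != 4L)
    msg <- c(msg, "bold must be a 4D array")
  if (!identical(dim(object@bold)[1:3], dim(object@mask)))
    msg <- c(msg, "mask grid must match bold grid")
  if (sum(object@runLengths) != dim(object@bold)[4L])
    msg <- c(msg, "runLengths must sum to the bold time dimension")
  need <- c("onset", "duration", "run", "trial_type")
  if (!all(need %in% names(object@trials)))
    msg <- c(msg, "trials must have onset, duration, run, trial_type")
  else {
    if (!all(object@trials$trial_type %in% c("true", "false")))
      msg <- c(msg, "trial_type must be 'true' or 'false'")
    for (r in unique(object@trials$run)) {
      on <- object@trials$onset[object@trials$run == r]
      if (any(diff(on) <= 0))
        msg <- c(msg, sprintf("onsets not strictly increasing in run %s", r))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Trial-window tensor
#'
#' The decoder's input: normalized signal, trial-locked, temporally smoothed
#' into seven overlapping windows centred 2--14 s after sentence onset.
#'
#' @slot values numeric array, trials x voxels x 7 windows, z-units.
#' @slot windowTimes numeric(7), window centres in seconds post-onset.
#' @slot voxelIndex integer, linear grid index of each voxel column.
#' @slot gridDim integer(3), dimensions of the originating voxel grid.
#' @slot trials trial table (see [SubjectData-class]).
#' @export
setClass("TrialTensor", representation(
  values = "array",
  windowTimes = "numeric",
  voxelIndex = "integer",
  gridDim = "integer",
  trials = "data.frame"
))

setValidity("TrialTensor", function(object) {
  msg <- character(0)
  d <- dim(object@values)
  if (length(d) != 3L || d[3L] != 7L)
    msg <- c(msg, "values must be trials x voxels x 7")
  if (!isTRUE(all.equal(object@windowTimes, WINDOW_TIMES)))
    msg <- c(msg, "windowTimes must be 2,4,...,14 s")
  if (length(object@voxelIndex) != d[2L])
    msg <- c(msg, "voxelIndex length must match voxel dimension")
  if (nrow(object@trials) != d[1L])
    msg <- c(msg, "trial table rows must match trial dimension")
  if (length(msg)) msg else TRUE
})

#' Per-voxel encoding model
#'
#' Ordinary least-squares fit, per voxel, of signal on the condition
#' regressor x = +1 (true) / -1 (false) with intercept. The slope is the
#' scalar parameter describing how strongly the truthfulness dimension
#' modulates a voxel; R-squared on the training trials ranks voxels for
#' selection.
#'
#' @slot weights per-voxel slope (z-units per condition unit).
#' @slot intercepts per-voxel offset.
#' @slot r2 per-voxel coefficient of determination in [0, 1].
#' @slot voxelIndex linear grid index of each voxel.
#' @slot gridDim integer(3).
#' @export
setClass("EncodingModel", representation(
  weights = "numeric",
  intercepts = "numeric",
  r2 = "numeric",
  voxelIndex = "integer",
  gridDim = "integer"
))

setValidity("EncodingModel", function(object) {
  msg <- character(0)
  n <- length(object@weights)
  if (length(object@intercepts) != n || length(object@r2) != n ||
      length(object@voxelIndex) != n)
    msg <- c(msg, "weights, intercepts, r2, voxelIndex must be parallel")
  if (any(object@r2 < -1e-10 | object@r2 > 1 + 1e-10, na.rm = TRUE))
    msg <- c(msg, "r2 must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Selected voxel set
#'
#' Result of ranking voxels by encoding-model R-squared, keeping the top
#' `nTop` and dropping small clusters.
#'
#' @slot selected integer, linear grid indices of retained voxels.
#' @slot gridDim integer(3).
#' @slot clusters data.frame with one row per retained cluster (size and
#'   bounding information).
#' @export
setClass("VoxelSelection", representation(
  selected = "integer",
  gridDim = "integer",
  clusters = "data.frame"
))

#' Single-subject decoding result
#'
#' Per-window accuracies over all leave-two-out folds, bootstrap standard
#' errors, the per-window decoding maps (full-data voxel selections), the
#' best window, and (after [applyRankTest()]) permutation p-values.
#'
#' @slot accuracy numeric(7), fraction of correct folds per window.
#' @slot se numeric(7), bootstrap standard errors.
#' @slot foldOutcomes folds x 7 integer matrix of 0/1 correctness flags.
#' @slot maps list of 7 integer vectors: selected voxel linear indices.
#' @slot gridDim integer(3).
#' @slot bestWindow seconds; earliest window attaining the maximum accuracy.
#' @slot pValues numeric(7); NA until a null distribution is applied.
#' @slot subject subject identifier.
#' @export
setClass("DecodingResult", representation(
  accuracy = "numeric",
  se = "numeric",
  foldOutcomes = "matrix",
  maps = "list",
  gridDim = "integer",
  bestWindow = "numeric",
  pValues = "numeric",
  subject = "character"
))

setValidity("DecodingResult", function(object) {
  msg <- character(0)
  if (length(object@accuracy) != 7L) msg <- c(msg, "7 window accuracies required")
  if (ncol(object@foldOutcomes) != 7L) msg <- c(msg, "foldOutcomes needs 7 columns")
  acc <- colMeans(object@foldOutcomes)
  if (!isTRUE(all.equal(unname(acc), unname(object@accuracy))))
    msg <- c(msg, "accuracy must equal the mean of foldOutcomes")
  if (!(object@bestWindow %in% WINDOW_TIMES))
    msg <- c(msg, "bestWindow must be one of 2,4,...,14 s")
  if (length(msg)) msg else TRUE
})

#' Empirical null distribution of decoding accuracies
#'
#' Accuracies obtained by re-running the full decoding with training labels
#' shuffled: `nPerWindow` replicates per window, pooled across the seven
#' windows into one common reference distribution.
#'
#' @slot values nPerWindow x 7 numeric matrix, one column per window.
#' @slot windowTimes numeric(7).
#' @slot seed seed the replicates were drawn with.
#' @export
setClass("NullDistribution", representation(
  values = "matrix",
  windowTimes = "numeric",
  seed = "integer"
))

setValidity("NullDistribution", function(object) {
  if (ncol(object@values) != 7L) "values must have 7 columns (windows)"
  else TRUE
})

#' Group posterior probability map
#'
#' Per voxel, the fraction of subjects whose decoding map contains the voxel.
#'
#' @slot prob 3D numeric array of fractions in [0, 1].
#' @slot nSubjects number of subjects combined.
#' @slot windows numeric, the per-subject window (s) each map was taken at.
#' @export
setClass("ProbabilityMap", representation(
  prob = "array",
  nSubjects = "integer",
  windows = "numeric"
))

setValidity("ProbabilityMap", function(object) {
  p <- object@prob
  k <- p * object@nSubjects
  if (any(p < 0 | p > 1)) "probabilities outside [0, 1]"
  else if (max(abs(k - round(k))) > 1e-8)
    "probabilities must be multiples of 1/nSubjects"
  else TRUE
})

#' Valence (wedding vs funeral) group comparison
#'
#' @slot uStat Mann-Whitney U for the best-window comparison.
#' @slot uP exact two-tailed p-value.
#' @slot diceMatrix subject x subject Sorensen-Dice coefficients.
#' @slot R ratio of mean within-group to mean between-group Dice.
#' @slot ci numeric(2): 2.5th and 97.5th percentiles of permuted R.
#' @slot nPerm number of label permutations.
#' @slot decision "group-specific maps" iff R falls outside the CI.
#' @export
setClass("GroupComparison", representation(
  uStat = "numeric",
  uP = "numeric",
  diceMatrix = "matrix",
  R = "numeric",
  ci = "numeric",
  nPerm = "integer",
  decision = "character"
))

setValidity("GroupComparison", function(object) {
  d <- object@diceMatrix
  msg <- character(0)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d))))
    msg <- c(msg, "diceMatrix must be square and symmetric")
  if (any(abs(diag(d) - 1) > 1e-8))
    msg <- c(msg, "diceMatrix diagonal must be 1")
  if (length(msg)) msg else TRUE
})
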