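#' Pipeline parameters
#'
#' Validated parameter set for [runPipeline()]. Defaults are the analysis
#' constants used throughout: 2,000 selected voxels, cluster filter > 20
#' voxels during selection and >= 20 in the group map, group probability
#' threshold 0.33, 1,000 bootstrap resamples, 100 null permutations per
#' window, and 10,000 iterations for the sparseness and R permutation
#' tests.
#'
#' @param nTop voxels retained by the R-squared ranking.
#' @param minClusterSelect minimum cluster size kept during voxel selection
#'   (strictly-larger-than-20 rule: 21).
#' @param minClusterGroup minimum cluster size in the thresholded group map.
#' @param pThresh group probability threshold (strict >).
#' @param nBoot bootstrap resamples for accuracy SEs.
#' @param nPermNull null permutations per window.
#' @param nPermGroup sparseness-test iterations.
#' @param nPermR R confidence-interval iterations.
#' @param connectivity cluster connectivity: 6, 18 or 26.
#' @return a validated named list.
#' @export
pipelineParams <- function(nTop = 2000L, minClusterSelect = 21L,
                           minClusterGroup = 20L, pThresh = 0.33,
                           nBoot = 1000L, nPermNull = 100L,
                           nPermGroup = 10000L, nPermR = 10000L,
                           connectivity = 6L) {
  p <- list(nTop = as.integer(nTop),
            minClusterSelect = as.integer(minClusterSelect),
            minClusterGroup = as.integer(minClusterGroup),
            pThresh = as.numeric(pThresh),
            nBoot = as.integer(nBoot),
            nPermNull = as.integer(nPermNull),
            nPermGroup = as.integer(nPermGroup),
            nPermR = as.integer(nPermR),
            connectivity = as.integer(connectivity))
  counts <- unlist(p[c("nTop", "minClusterSelect", "minClusterGroup",
                       "nBoot", "nPermNull", "nPermGroup", "nPermR")])
  if (any(counts < 1L)) stop("all counts must be positive")
  if (p$pThresh <= 0 || p$pThresh >= 1) stop("pThresh must be in (0, 1)")
  if (!p$connectivity %in% c(6L, 18L, 26L))
    stop("connectivity must be 6, 18 or 26")
  p
}

## Decode + null + p-values for one subject; returns the pieces the group
## stages need. Shared by runPipeline and the tests.
.analyzeSubject <- function(subject, params, seed) {
  tensor <- buildTrialTensor(subject)
  res <- decodeSubject(tensor,
                       nTop = params$nTop,
                       minCluster = params$minClusterSelect,
                       connectivity = params$connectivity,
                       nBoot = params$nBoot, seed = seed,
                       subject = subject@subject)
  null <- buildNull(tensor, nPerWindow = params$nPermNull, seed = seed,
                    nTop = params$nTop,
                    minCluster = params$minClusterSelect,
                    connectivity = params$connectivity)
  res <- applyRankTest(res, null)
  list(result = res, null = null)
}

#' Run the full analysis pipeline
#'
#' Drives every stage end to end over a cohort: per subject, preprocessing
#' (per-run voxel normalization, trial-window extraction, temporal
#' smoothing), leave-two-out decoding at the seven windows with bootstrap
#' SEs, the 700-value permutation null and rank-test p-values; then, across
#' subjects, the posterior probability map at the best-accuracy windows,
#' its thresholded cluster table, the sparseness permutation test, and the
#' wedding/funeral valence comparison. Fully reproducible from
#' `(input, seed)`.
#'
#' @param cohort a [CohortSpec-class] (subjects are generated one at a time
#'   to bound memory) or a list of [SubjectData-class] objects.
#' @param params a [pipelineParams()] list.
#' @param seed master seed for all randomness (bootstrap, null, group and R
#'   permutations run on independent substreams derived from it).
#' @param outDir optional output directory; if given, writes
#'   `subject_table.tsv` (per-subject best accuracy, SE, window, p),
#'   `cluster_table.tsv`, `sparseness.tsv` (observed/null quantile curves),
#'   `dice_matrix.tsv`, `group_probability_map.nii.gz` + voxel list, and
#'   `summary.json`.
#' @param verbose print progress per subject.
#' @return a list (invisible when `outDir` is given) with elements
#'   `subjects` (data.frame), `results` (list of [DecodingResult-class]),
#'   `probabilityMap`, `clusters`, `sparseness`, `valence`.
#' @export
runPipeline <- function(cohort, params = pipelineParams(), seed = 1L,
                        outDir = NULL, verbose = FALSE) {
  if (is(cohort, "CohortSpec")) {
    n <- cohort@nSubjects
    groups <- rep(c("wedding", "funeral"), cohort@groupSizes)
    getSubject <- function(i) {
      s <- generateSubject(cohort, i)
      s@group <- groups[i]
      s
    }
    gridDim <- cohort@gridShape
  } else {
    stopifnot(is.list(cohort), all(vapply(cohort, is, TRUE, "SubjectData")))
    n <- length(cohort)
    getSubject <- function(i) cohort[[i]]
    gridDim <- dim(cohort[[1L]]@bold)[1:3]
  }

  results <- vector("list", n)
  allMaps <- vector("list", n)
  groupsOut <- character(n)
  for (i in seq_len(n)) {
    subj <- getSubject(i)
    groupsOut[i] <- subj@group
    step <- tryCatch(
      .analyzeSubject(subj, params, .substreamSeed(seed, "generic", i)),
      error = function(e) stop("subject ", subj@subject,
                               " (decode stage): ", conditionMessage(e)))
    results[[i]] <- step$result
    allMaps[[i]] <- step$result@maps
    if (verbose)
      message(subj@subject, ": best ", step$result@bestWindow, " s, acc ",
              round(max(step$result@accuracy), 3), ", p ",
              signif(min(step$result@pValues), 3))
  }

  bestW <- vapply(results, function(r) r@bestWindow, numeric(1))
  bestIdx <- match(bestW, WINDOW_TIMES)
  bestAcc <- vapply(seq_len(n), function(i)
    results[[i]]@accuracy[bestIdx[i]], numeric(1))
  bestSE <- vapply(seq_len(n), function(i)
    results[[i]]@se[bestIdx[i]], numeric(1))
  bestP <- vapply(seq_len(n), function(i)
    results[[i]]@pValues[bestIdx[i]], numeric(1))
  subjects <- data.frame(
    subject = vapply(results, function(r) r@subject, character(1)),
    group = groupsOut,
    best_window_s = bestW,
    accuracy = bestAcc,
    se = bestSE,
    p = bestP,
    significant = bestP < 0.05)

  bestMaps <- lapply(seq_len(n), function(i) allMaps[[i]][[bestIdx[i]]])
  pmap <- buildProbabilityMap(bestMaps, gridDim = gridDim, windows = bestW)
  thr <- thresholdMap(pmap, pThresh = params$pThresh,
                      minCluster = params$minClusterGroup,
                      connectivity = params$connectivity)
  sparse <- sparsenessTest(allMaps, bestW, gridDim = gridDim,
                           nIter = params$nPermGroup, seed = seed)
  val <- if (length(unique(groupsOut)) == 2L)
    valenceComparison(bestMaps, groupsOut, bestW,
                      nPerm = params$nPermR, seed = seed)
  else NULL

  report <- list(subjects = subjects, results = results,
                 probabilityMap = pmap, thresholdedMap = thr$map,
                 clusters = thr$clusters, sparseness = sparse,
                 valence = val)
  if (!is.null(outDir)) {
    .writePipelineReport(report, outDir, gridDim)
    return(invisible(report))
  }
  report
}

.writePipelineReport <- function(report, outDir, gridDim) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(outDir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(report$subjects, "subject_table.tsv")
  tsv(report$clusters, "cluster_table.tsv")
  sp <- report$sparseness
  tsv(data.frame(threshold = sp$thresholds,
                 observed = sp$observedCounts,
                 null_q025 = apply(sp$nullCounts, 2L, quantile, 0.025),
                 null_median = apply(sp$nullCounts, 2L, quantile, 0.5),
                 null_q975 = apply(sp$nullCounts, 2L, quantile, 0.975),
                 p = sp$pPerThreshold),
      "sparseness.tsv")
  RNifti::writeNifti(RNifti::asNifti(report$probabilityMap@prob),
                     file.path(outDir, "group_probability_map.nii.gz"))
  writeMap(report$thresholdedMap, file.path(outDir, "group_map_thresholded"))
  summary <- list(
    n_subjects = nrow(report$subjects),
    n_significant = sum(report$subjects$significant),
    mean_best_accuracy = mean(report$subjects$accuracy),
    best_window_mean_s = mean(report$subjects$best_window_s),
    best_window_sd_s = sd(report$subjects$best_window_s))
  if (!is.null(report$valence)) {
    tsv(as.data.frame(report$valence@diceMatrix), "dice_matrix.tsv")
    summary <- c(summary, list(
      mann_whitney_U = report$valence@uStat,
      mann_whitney_p = report$valence@uP,
      R = report$valence@R,
      R_ci = report$valence@ci,
      valence_decision = report$valence@decision))
  }
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
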