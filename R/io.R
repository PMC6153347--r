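## File interfaces: NIfTI volumes via RNifti, trial tables as BIDS-style
## events TSV (onset, duration, run, trial_type), maps additionally as
## diff-friendly sparse voxel-list TSVs.

#' Write a subject dataset to disk
#'
#' Writes `<prefix>_bold.nii.gz` (4D), `<prefix>_mask.nii.gz`,
#' `<prefix>_events.tsv`, and — for synthetic subjects —
#' `<prefix>_truthmask.nii.gz` with the planted informative voxels, plus a
#' small JSON sidecar (TR, run lengths, group, planted latency).
#'
#' @param subject a [SubjectData-class].
#' @param dir output directory (created if missing).
#' @param prefix file prefix; defaults to the subject id.
#' @return invisibly, the paths written.
#' @export
writeSubjectData <- function(subject, dir, prefix = subject@subject) {
  stopifnot(is(subject, "SubjectData"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(suffix) file.path(dir, paste0(prefix, suffix))
  bold <- RNifti::asNifti(subject@bold)
  RNifti::pixdim(bold) <- c(1, 1, 1, subject@tr)
  RNifti::writeNifti(bold, p("_bold.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(subject@mask * 1L), p("_mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(subject@infoMask * 1L),
                     p("_truthmask.nii.gz"))
  write.table(subject@trials, p("_events.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(tr = subject@tr,
                            run_lengths = subject@runLengths,
                            group = subject@group,
                            planted_latency = subject@latency),
                       p("_meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(p("_bold.nii.gz"), p("_mask.nii.gz"), p("_truthmask.nii.gz"),
              p("_events.tsv"), p("_meta.json")))
}

#' Read a subject dataset from disk
#'
#' Loads a 4D time series, mask and events TSV, validating that the grids
#' agree, that `trial_type` holds only "true"/"false", and that onsets
#' increase strictly within each run. Validation failures name the file and
#' row. Unknown extra event columns are kept.
#'
#' @param boldPath path to the 4D NIfTI.
#' @param maskPath path to the 3D mask NIfTI.
#' @param eventsPath path to the events TSV (columns onset, duration, run,
#'   trial_type).
#' @param tr repetition time in seconds; if `NULL`, taken from the NIfTI
#'   header (pixdim of the 4th dimension).
#' @param runLengths TRs per run; if `NULL`, read from `<bold>_meta.json`
#'   next to the bold file, else a single run spanning the series is
#'   assumed.
#' @param group,subject metadata labels.
#' @return a [SubjectData-class] (ground-truth slots empty).
#' @export
readSubjectData <- function(boldPath, maskPath, eventsPath, tr = NULL,
                            runLengths = NULL, group = "unknown",
                            subject = "subject") {
  bold <- RNifti::readNifti(boldPath)
  if (length(dim(bold)) != 4L)
    stop(boldPath, ": expected a 4D time series")
  mask <- RNifti::readNifti(maskPath)
  if (!identical(dim(mask), dim(bold)[1:3]))
    stop(maskPath, ": mask grid ", paste(dim(mask), collapse = "x"),
         " does not match time-series grid ",
         paste(dim(bold)[1:3], collapse = "x"))
  ev <- read.delim(eventsPath, sep = "\t", stringsAsFactors = FALSE)
  need <- c("onset", "duration", "run", "trial_type")
  miss <- setdiff(need, names(ev))
  if (length(miss))
    stop(eventsPath, ": missing column(s) ", paste(miss, collapse = ", "))
  bad <- which(!ev$trial_type %in% c("true", "false"))
  if (length(bad))
    stop(eventsPath, ": row ", bad[1L], ": unknown trial_type '",
         ev$trial_type[bad[1L]], "'")
  for (r in unique(ev$run)) {
    on <- ev$onset[ev$run == r]
    if (any(diff(on) <= 0))
      stop(eventsPath, ": onsets not strictly increasing in run ", r)
  }
  if (is.null(tr)) {
    pd <- RNifti::pixdim(bold)
    tr <- if (length(pd) >= 4L && pd[4L] > 0) pd[4L] else 2
  }
  if (is.null(runLengths)) {
    metaPath <- sub("_bold\\.nii(\\.gz)?$", "_meta.json", boldPath)
    runLengths <- if (file.exists(metaPath))
      as.integer(jsonlite::read_json(metaPath)$run_lengths)
    else dim(bold)[4L]
  }
  new("SubjectData",
      bold = array(as.numeric(bold), dim = dim(bold)),
      mask = array(as.numeric(mask) != 0, dim = dim(mask)),
      trials = ev, runLengths = as.integer(runLengths),
      group = group,
      infoMask = array(FALSE, dim = dim(mask)),
      latency = NA_real_, tr = as.numeric(tr), subject = subject)
}

#' Write a binary map as NIfTI plus a sparse voxel-list TSV
#'
#' @param map logical 3D array or linear index vector (with `gridDim`).
#' @param path output path without extension; writes `<path>.nii.gz` and
#'   `<path>_voxels.tsv` (columns x, y, z, 1-based grid coordinates).
#' @param gridDim required when `map` is an index vector.
#' @return invisibly, the two paths.
#' @export
writeMap <- function(map, path, gridDim = NULL) {
  if (!is.array(map)) {
    stopifnot(!is.null(gridDim))
    map <- .logicalMap(as.integer(map), gridDim)
  }
  RNifti::writeNifti(RNifti::asNifti(map * 1L), paste0(path, ".nii.gz"))
  co <- arrayInd(which(map), dim(map))
  write.table(data.frame(x = co[, 1L], y = co[, 2L], z = co[, 3L]),
              paste0(path, "_voxels.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(paste0(path, ".nii.gz"), paste0(path, "_voxels.tsv")))
}
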