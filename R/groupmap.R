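## Group-level posterior probability map and its sparseness permutation
## test. The map records, per voxel, the fraction of subjects whose
## decoding map (taken at each subject's best-accuracy window) includes the
## voxel; the sparseness test asks whether that combination yields fewer
## suprathreshold voxels than combinations built from randomly chosen
## per-subject windows — i.e., whether the informative regions are stable
## across subjects.

#' Build the group posterior probability map
#'
#' @param maps list of per-subject binary maps, each either a logical 3D
#'   array (all on the same grid) or an integer vector of linear voxel
#'   indices (then `gridDim` is required).
#' @param gridDim integer(3), required when `maps` holds index vectors.
#' @param windows optional numeric: per-subject window (s) each map came
#'   from, recorded in the result.
#' @return a [ProbabilityMap-class]: `prob(v)` = share of subjects whose
#'   map contains voxel `v`.
#' @export
buildProbabilityMap <- function(maps, gridDim = NULL, windows = numeric(0)) {
  stopifnot(length(maps) >= 1L)
  if (is.array(maps[[1L]])) {
    gridDim <- dim(maps[[1L]])
    for (m in maps)
      if (!identical(dim(m), gridDim)) stop("subject maps on different grids")
    counts <- Reduce(`+`, lapply(maps, function(m) m * 1))
  } else {
    if (is.null(gridDim)) stop("gridDim required for index-vector maps")
    counts <- array(0, dim = gridDim)
    for (m in maps) counts[m] <- counts[m] + 1
  }
  new("ProbabilityMap", prob = counts / length(maps),
      nSubjects = length(maps), windows = as.numeric(windows))
}

#' Threshold and cluster the probability map
#'
#' Keeps voxels with probability strictly above `pThresh` (the default 0.33
#' means "informative in at least 5 of 14 subjects"), labels connected
#' clusters, and drops clusters smaller than `minCluster` voxels (non-strict:
#' 20-voxel clusters survive the default). Returns the thresholded map and a
#' cluster table with size, centre of mass and peak-probability voxel,
#' sorted by size descending.
#'
#' @param pmap a [ProbabilityMap-class].
#' @param pThresh probability threshold (strict >).
#' @param minCluster minimum retained cluster size (voxels, >=).
#' @param connectivity 6, 18 or 26.
#' @return list with `map` (logical 3D array) and `clusters` (data.frame:
#'   size, cmX, cmY, cmZ, peakX, peakY, peakZ, peakProb).
#' @export
thresholdMap <- function(pmap, pThresh = 0.33, minCluster = 20L,
                         connectivity = 6L) {
  stopifnot(is(pmap, "ProbabilityMap"), pThresh > 0, pThresh < 1)
  dims <- dim(pmap@prob)
  idx <- which(pmap@prob > pThresh)
  empty <- data.frame(size = integer(0), cmX = numeric(0), cmY = numeric(0),
                      cmZ = numeric(0), peakX = integer(0), peakY = integer(0),
                      peakZ = integer(0), peakProb = numeric(0))
  if (length(idx) == 0L)
    return(list(map = array(FALSE, dims), clusters = empty))
  comp <- clusterLabels(idx, dims, connectivity)
  sizes <- tabulate(comp)
  keep <- which(sizes >= minCluster)
  if (length(keep) == 0L)
    return(list(map = array(FALSE, dims), clusters = empty))
  rows <- lapply(keep, function(k) {
    vox <- idx[comp == k]
    co <- arrayInd(vox, dims)
    pk <- vox[which.max(pmap@prob[vox])]
    pkco <- arrayInd(pk, dims)
    data.frame(size = length(vox),
               cmX = mean(co[, 1L]), cmY = mean(co[, 2L]), cmZ = mean(co[, 3L]),
               peakX = pkco[1L], peakY = pkco[2L], peakZ = pkco[3L],
               peakProb = max(pmap@prob[vox]),
               minIndex = min(vox))
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$size, tab$minIndex), , drop = FALSE]
  keptIdx <- idx[comp %in% keep]
  rownames(tab) <- NULL
  list(map = .logicalMap(keptIdx, dims),
       clusters = tab[, setdiff(names(tab), "minIndex")])
}

## Suprathreshold voxel counts at thresholds k/nSubjects, k = 1..nSubjects,
## from a vector of per-voxel subject counts. count[k] = #{v : count(v) >= k}
## (equivalently prob > (k-1)/n), non-increasing in k.
.countsByThreshold <- function(counts, nSubjects) {
  tab <- tabulate(counts[counts > 0], nbins = nSubjects)
  rev(cumsum(rev(tab)))
}

#' Sparseness permutation test of the group map
#'
#' Null hypothesis: the per-subject window choice does not matter — a group
#' map built from the observed (best-accuracy) windows is no more spatially
#' concentrated than one built from randomly drawn windows. Each iteration
#' draws one window uniformly per subject, builds the probability map, and
#' records the total suprathreshold voxel count at every probability
#' threshold k/n (k = 1..n subjects). The observed combination is tested
#' one-sided: low counts (high overlap) are evidence of stability, so
#' `p = (1 + #\{null <= observed\}) / (1 + nIter)` per threshold. The seven
#' fixed-window combinations (every subject at the same window) are
#' evaluated against the same null for reference.
#'
#' @param subjectMaps list over subjects; each element a list of 7 maps
#'   (logical array or linear-index vector), one per window.
#' @param observedWindows numeric: each subject's best window in seconds.
#' @param gridDim integer(3); required if maps are index vectors.
#' @param nIter permutation iterations.
#' @param seed RNG seed (group-permutation substream).
#' @return list with `thresholds` (k/n), `observedCounts`, `nullCounts`
#'   (nIter x thresholds), `pPerThreshold`, `fixedWindowCounts`
#'   (7 x thresholds) and `fixedWindowP`.
#' @export
sparsenessTest <- function(subjectMaps, observedWindows, gridDim = NULL,
                           nIter = 10000L, seed = 1L) {
  nSubj <- length(subjectMaps)
  stopifnot(nSubj >= 2L, length(observedWindows) == nSubj,
            all(vapply(subjectMaps, length, 1L) == 7L))
  first <- subjectMaps[[1L]][[1L]]
  if (is.array(first)) gridDim <- dim(first)
  if (is.null(gridDim)) stop("gridDim required for index-vector maps")
  nVox <- prod(gridDim)
  ## column s + nSubj*(w-1)? lay out as [subject, window] columns
  M <- matrix(0L, nVox, nSubj * 7L)
  for (s in seq_len(nSubj)) for (w in 1:7) {
    m <- subjectMaps[[s]][[w]]
    idx <- if (is.array(m)) which(m) else as.integer(m)
    M[idx, (s - 1L) * 7L + w] <- 1L
  }
  countsFor <- function(wsel) {
    cols <- (seq_len(nSubj) - 1L) * 7L + wsel
    .countsByThreshold(rowSums(M[, cols, drop = FALSE]), nSubj)
  }
  obsW <- match(observedWindows, WINDOW_TIMES)
  if (anyNA(obsW)) stop("observedWindows must be window centres (2..14 s)")
  observed <- countsFor(obsW)
  nullCounts <- .withSeed(.substreamSeed(seed, "groupperm"), {
    t(vapply(seq_len(nIter),
             function(i) countsFor(sample.int(7L, nSubj, replace = TRUE)),
             numeric(nSubj)))
  })
  p <- vapply(seq_len(nSubj), function(k)
    (1 + sum(nullCounts[, k] <= observed[k])) / (1 + nIter), numeric(1))
  fixed <- t(vapply(1:7, function(w) countsFor(rep(w, nSubj)),
                    numeric(nSubj)))
  fixedP <- t(apply(fixed, 1L, function(oc)
    vapply(seq_len(nSubj), function(k)
      (1 + sum(nullCounts[, k] <= oc[k])) / (1 + nIter), numeric(1))))
  list(thresholds = seq_len(nSubj) / nSubj,
       observedCounts = observed,
       nullCounts = nullCounts,
       pPerThreshold = p,
       fixedWindowCounts = fixed,
       fixedWindowP = fixedP,
       nIter = as.integer(nIter))
}
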