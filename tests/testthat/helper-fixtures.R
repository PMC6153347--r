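## Shared fixtures: small cohort specs and hand-built tensors.

tinySpec <- function(...) {
  args <- list(nSubjects = 2L, groupSizes = c(1L, 1L), nTrials = 8L,
               nRuns = 2L, gridShape = c(8L, 8L, 8L), maskFraction = 0.5,
               nInformative = 42L, latency = 8, effectSize = 2,
               seed = 101L)
  do.call(cohortSpec, utils::modifyList(args, list(...)))
}

## TrialTensor straight from a trials x voxels x 7 array (or a matrix
## replicated over windows), bypassing the generator.
makeTensor <- function(values, labels, gridDim = NULL, voxelIndex = NULL) {
  if (length(dim(values)) == 2L)
    values <- array(rep(values, 7L), dim = c(dim(values), 7L))
  nv <- dim(values)[2L]
  if (is.null(gridDim)) gridDim <- c(nv, 1L, 1L)
  if (is.null(voxelIndex)) voxelIndex <- seq_len(nv)
  trials <- data.frame(onset = 4 + 18 * (seq_len(dim(values)[1L]) - 1),
                       duration = 5.5, run = 1L,
                       trial_type = labels, stringsAsFactors = FALSE)
  new("TrialTensor", values = values, windowTimes = seq(2, 14, 2),
      voxelIndex = as.integer(voxelIndex), gridDim = as.integer(gridDim),
      trials = trials)
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
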