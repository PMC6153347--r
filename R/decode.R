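## Single-subject encoding-model decoder.
##
## Per voxel, signal at one temporal window is modelled as
##   y = a + b * x,   x = +1 (true) / -1 (false),
## fitted by OLS on the training trials of each leave-two-stimuli-out fold.
## The 2,000 voxels with the highest training R^2 (clusters > 20 voxels)
## are selected; the model predicts the activation pattern of the two
## left-out trials and the fold is scored by cosine-similarity matching.

#' Enumerate leave-two-stimuli-out folds
#'
#' All ordered (true, false) trial pairs: each fold leaves out exactly one
#' true and one false trial and trains on the rest. Order is deterministic:
#' true index ascending, false index ascending within it.
#'
#' @param labels character/factor/logical trial labels; "true"/TRUE marks
#'   the true class.
#' @return integer matrix with columns `trueIdx`, `falseIdx`; one row per
#'   fold (`n_T * n_F` rows).
#' @examples
#' nrow(enumerateFolds(rep(c("true", "false"), each = 24)))  # 576
#' @export
enumerateFolds <- function(labels) {
  isT <- .isTrueLabel(labels)
  tIdx <- which(isT); fIdx <- which(!isT)
  if (length(tIdx) < 2L || length(fIdx) < 2L)
    stop("need at least 2 trials of each class for leave-two-out CV")
  cbind(trueIdx = rep(tIdx, each = length(fIdx)),
        falseIdx = rep(fIdx, times = length(tIdx)))
}

.isTrueLabel <- function(labels) {
  if (is.logical(labels)) return(labels)
  lv <- unique(as.character(labels))
  if (!all(lv %in% c("true", "false")))
    stop("labels must be 'true'/'false' (got: ", paste(lv, collapse = ", "), ")")
  as.character(labels) == "true"
}

## Vectorised per-voxel OLS of y on binary x in {+1, -1} with intercept.
## Y: trials x voxels; x: +1/-1 per trial. Returns slope b, intercept a,
## and R^2 (0 for zero-variance voxels).
.fitEnc <- function(Y, x) {
  n <- length(x)
  npos <- sum(x > 0); nneg <- n - npos
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present in the training set")
  Sp <- colSums(Y[x > 0, , drop = FALSE])
  Sn <- colSums(Y[x < 0, , drop = FALSE])
  Q <- colSums(Y * Y)
  .fitEncFromSums(Sp, Sn, Q, npos, nneg)
}

## Same fit from sufficient statistics (class sums, total sum of squares,
## class counts) — the per-fold fast path updates these incrementally.
.fitEncFromSums <- function(Sp, Sn, Q, npos, nneg) {
  n <- npos + nneg
  xbar <- (npos - nneg) / n
  Sy <- Sp + Sn
  ybar <- Sy / n
  Sxy <- (Sp - Sn) - n * xbar * ybar
  Sxx <- 4 * npos * nneg / n
  Syy <- Q - n * ybar^2
  b <- Sxy / Sxx
  r2 <- Sxy^2 / (Sxx * pmax(Syy, .Machine$double.eps))
  bad <- Syy <= 1e-12
  b[bad] <- 0
  r2[bad] <- 0
  r2[r2 > 1] <- 1                     # guard numerical overshoot
  list(weights = b, intercepts = ybar - b * xbar, r2 = r2)
}

#' Fit the per-voxel encoding model
#'
#' OLS regression, per voxel, of the window signal on the condition
#' regressor x = +1 (true) / -1 (false) with intercept. R-squared is
#' computed on the same (training) trials. Zero-variance voxels get weight
#' 0 and R-squared 0.
#'
#' @param Y trials x voxels numeric matrix (signal at one window).
#' @param labels trial labels (see [enumerateFolds()]).
#' @param voxelIndex,gridDim voxel geometry carried into the model object
#'   (defaults cover matrix-only use).
#' @return an [EncodingModel-class].
#' @export
fitEncoding <- function(Y, labels, voxelIndex = seq_len(ncol(Y)),
                        gridDim = c(ncol(Y), 1L, 1L)) {
  x <- ifelse(.isTrueLabel(labels), 1, -1)
  fit <- .fitEnc(Y, x)
  new("EncodingModel", weights = fit$weights, intercepts = fit$intercepts,
      r2 = fit$r2, voxelIndex = as.integer(voxelIndex),
      gridDim = as.integer(gridDim))
}

## Fast path: top-nTop voxels by r2 (ties by ascending voxel index), then
## drop face-connected clusters smaller than minCluster. Returns positions
## into the r2/voxelIndex vectors.
.selectTop <- function(r2, voxelIndex, gridDim, nTop, minCluster,
                       connectivity = 6L) {
  v <- length(r2)
  top <- if (v <= nTop) seq_len(v)
         else order(r2, decreasing = TRUE, method = "radix")[seq_len(nTop)]
  lin <- voxelIndex[top]
  keepLin <- .clusterFilter(lin, gridDim, minCluster, connectivity)
  top[match(keepLin, lin)]
}

#' Select informative voxels
#'
#' Ranks in-mask voxels by encoding-model R-squared, keeps the `nTop`
#' highest (ties broken by ascending linear voxel index), partitions them
#' into connected clusters and drops clusters smaller than `minCluster`
#' voxels. The default `minCluster = 21` implements the "cluster size
#' larger than 20 voxels" rule used during decoding. If the mask holds
#' fewer than `nTop` voxels, all of them enter the ranking (a message is
#' emitted).
#'
#' @param model an [EncodingModel-class].
#' @param nTop number of voxels to retain before cluster filtering.
#' @param minCluster minimum retained cluster size (voxels).
#' @param connectivity 6 (face, default), 18 or 26.
#' @return a [VoxelSelection-class].
#' @export
selectVoxels <- function(model, nTop = 2000L, minCluster = 21L,
                         connectivity = 6L) {
  stopifnot(is(model, "EncodingModel"))
  if (length(model@r2) < nTop)
    message("mask smaller than nTop (", length(model@r2),
            " < ", nTop, "): selecting from all voxels")
  pos <- .selectTop(model@r2, model@voxelIndex, model@gridDim,
                    nTop, minCluster, connectivity)
  lin <- model@voxelIndex[pos]
  if (length(lin)) {
    comp <- clusterLabels(lin, model@gridDim, connectivity)
    sizes <- tabulate(comp)
    clusters <- data.frame(cluster = seq_along(sizes), size = sizes)
  } else {
    clusters <- data.frame(cluster = integer(0), size = integer(0))
  }
  new("VoxelSelection", selected = as.integer(lin),
      gridDim = model@gridDim, clusters = clusters)
}

#' Predict the activation pattern for one condition
#'
#' Linear-model prediction `intercept + weight * x(label)` over the selected
#' voxels, x = +1 for "true", -1 for "false".
#'
#' @param model an [EncodingModel-class].
#' @param selection a [VoxelSelection-class] (subset of the model's voxels).
#' @param label "true" or "false".
#' @return numeric vector over the selected voxels.
#' @export
predictPattern <- function(model, selection, label) {
  stopifnot(is(model, "EncodingModel"), is(selection, "VoxelSelection"))
  pos <- match(selection@selected, model@voxelIndex)
  if (anyNA(pos)) stop("selection contains voxels outside the model")
  x <- if (identical(label, "true")) 1 else if (identical(label, "false")) -1
       else stop("label must be 'true' or 'false'")
  model@intercepts[pos] + model@weights[pos] * x
}

#' Score one left-out pair by cosine-similarity matching
#'
#' The two observed left-out patterns are assigned to the two predicted
#' patterns; the fold is correct iff the veridical assignment wins:
#' `cos(predT, obsT) + cos(predF, obsF) > cos(predT, obsF) + cos(predF, obsT)`.
#' An exact tie counts as incorrect (conservative). Cosine with a zero-norm
#' vector is defined as 0.
#'
#' @param predT,predF predicted patterns for the true / false condition.
#' @param obsT,obsF observed patterns of the left-out true / false trial.
#' @return logical: fold correct?
#' @export
matchPair <- function(predT, predF, obsT, obsF) {
  (.cosine(predT, obsT) + .cosine(predF, obsF)) >
    (.cosine(predT, obsF) + .cosine(predF, obsT))
}

## Core fold loop at one window.
## Y: trials x voxels; xTrain: +1/-1 labels used for TRAINING (equal to the
## true labels for the observed analysis, a permuted copy for the null);
## folds: matrix from enumerateFolds (always built from the TRUE labels).
## Returns integer vector of fold outcomes (1 = correct).
.decodeCore <- function(Y, xTrain, folds, voxelIndex, gridDim,
                        nTop, minCluster, connectivity) {
  SpAll <- colSums(Y[xTrain > 0, , drop = FALSE])
  SnAll <- colSums(Y[xTrain < 0, , drop = FALSE])
  QAll <- colSums(Y * Y)
  nposAll <- sum(xTrain > 0); nnegAll <- length(xTrain) - nposAll
  out <- integer(nrow(folds))
  for (k in seq_len(nrow(folds))) {
    t <- folds[k, 1L]; f <- folds[k, 2L]
    yt <- Y[t, ]; yf <- Y[f, ]
    Sp <- SpAll; Sn <- SnAll; npos <- nposAll; nneg <- nnegAll
    if (xTrain[t] > 0) { Sp <- Sp - yt; npos <- npos - 1L }
    else { Sn <- Sn - yt; nneg <- nneg - 1L }
    if (xTrain[f] > 0) { Sp <- Sp - yf; npos <- npos - 1L }
    else { Sn <- Sn - yf; nneg <- nneg - 1L }
    if (npos == 0L || nneg == 0L) { out[k] <- 0L; next }
    fit <- .fitEncFromSums(Sp, Sn, QAll - yt^2 - yf^2, npos, nneg)
    pos <- .selectTop(fit$r2, voxelIndex, gridDim, nTop, minCluster,
                      connectivity)
    if (length(pos) == 0L) { out[k] <- 0L; next }   # empty selection
    a <- fit$intercepts[pos]; b <- fit$weights[pos]
    ok <- matchPair(a + b, a - b, yt[pos], yf[pos])
    out[k] <- as.integer(ok)
  }
  out
}

#' Decode one temporal window
#'
#' Runs the full leave-two-stimuli-out procedure at one window: for every
#' fold, fit the encoding model on the 46 training trials, select voxels,
#' predict the two left-out patterns and score by cosine matching. The
#' subject's decoding map for the window is the voxel selection from a
#' model fitted on all trials.
#'
#' @param tensor a [TrialTensor-class].
#' @param window window centre in seconds (one of 2, 4, ..., 14).
#' @param nTop,minCluster,connectivity see [selectVoxels()].
#' @return list with `accuracy`, `outcomes` (integer per fold), and `map`
#'   (integer linear voxel indices of the full-data selection).
#' @export
decodeWindow <- function(tensor, window, nTop = 2000L, minCluster = 21L,
                         connectivity = 6L) {
  stopifnot(is(tensor, "TrialTensor"))
  w <- match(window, tensor@windowTimes)
  if (is.na(w)) stop("unknown window: ", window)
  Y <- tensor@values[, , w]
  labels <- tensor@trials$trial_type
  x <- ifelse(.isTrueLabel(labels), 1, -1)
  folds <- enumerateFolds(labels)
  outcomes <- .decodeCore(Y, x, folds, tensor@voxelIndex, tensor@gridDim,
                          nTop, minCluster, connectivity)
  full <- .fitEnc(Y, x)
  pos <- .selectTop(full$r2, tensor@voxelIndex, tensor@gridDim,
                    nTop, minCluster, connectivity)
  list(accuracy = mean(outcomes), outcomes = outcomes,
       map = as.integer(tensor@voxelIndex[pos]))
}

#' Bootstrap standard error of a decoding accuracy
#'
#' Resamples the fold outcomes with replacement `nBoot` times; the SE is the
#' standard deviation of the resampled accuracies.
#'
#' @param outcomes integer/logical vector of per-fold correctness flags.
#' @param nBoot number of bootstrap resamples.
#' @param seed RNG seed (caller's RNG state is preserved).
#' @return numeric standard error.
#' @export
bootstrapSE <- function(outcomes, nBoot = 1000L, seed = 1L) {
  n <- length(outcomes)
  stopifnot(n >= 2L)
  .withSeed(seed, {
    res <- matrix(sample(as.numeric(outcomes), n * nBoot, replace = TRUE),
                  n, nBoot)
    sd(colMeans(res))
  })
}

#' Best decoding window
#'
#' @param acc numeric(7) accuracies ordered by window (2, 4, ..., 14 s).
#' @return the window centre (s) with the highest accuracy; ties resolve to
#'   the earliest window.
#' @export
pickBestWindow <- function(acc) {
  stopifnot(length(acc) == 7L)
  WINDOW_TIMES[which.max(acc)]
}

#' Decode a subject across all seven windows
#'
#' Applies [decodeWindow()] at every window, attaches bootstrap standard
#' errors and the best window.
#'
#' @param tensor a [TrialTensor-class].
#' @param nTop,minCluster,connectivity see [selectVoxels()].
#' @param nBoot bootstrap resamples for the accuracy SE.
#' @param seed seed for the bootstrap substream.
#' @param subject subject identifier for reporting.
#' @return a [DecodingResult-class] (p-values NA until [applyRankTest()]).
#' @export
decodeSubject <- function(tensor, nTop = 2000L, minCluster = 21L,
                          connectivity = 6L, nBoot = 1000L, seed = 1L,
                          subject = "subject") {
  res <- lapply(WINDOW_TIMES, function(w)
    decodeWindow(tensor, w, nTop, minCluster, connectivity))
  acc <- vapply(res, `[[`, numeric(1), "accuracy")
  outcomes <- vapply(res, `[[`, integer(length(res[[1L]]$outcomes)),
                     "outcomes")
  se <- vapply(seq_along(res), function(i)
    bootstrapSE(res[[i]]$outcomes, nBoot,
                .substreamSeed(seed, "bootstrap", i)),
    numeric(1))
  new("DecodingResult",
      accuracy = acc, se = se, foldOutcomes = outcomes,
      maps = lapply(res, `[[`, "map"), gridDim = tensor@gridDim,
      bestWindow = pickBestWindow(acc),
      pValues = rep(NA_real_, 7L), subject = subject)
}
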