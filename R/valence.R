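## Valence comparison: does the emotional valence of the remembered event
## (wedding vs funeral group) change WHEN decoding peaks (best-window
## Mann-Whitney U) or WHERE it draws information from (Sorensen-Dice
## overlap of decoding maps, summarized by the within/between ratio R with
## a permutation confidence interval)?

#' Sorensen-Dice coefficient of two binary maps
#'
#' `2 |A intersect B| / (|A| + |B|)`. Two empty maps give 0 by convention.
#'
#' @param a,b logical arrays on the same grid, or integer vectors of linear
#'   voxel indices.
#' @return coefficient in [0, 1].
#' @examples
#' diceCoefficient(c(1:10), c(6:15))  # 0.5
#' @export
diceCoefficient <- function(a, b) {
  ia <- if (is.array(a) || is.logical(a)) which(a) else as.integer(a)
  ib <- if (is.array(b) || is.logical(b)) which(b) else as.integer(b)
  tot <- length(ia) + length(ib)
  if (tot == 0L) return(0)
  2 * length(intersect(ia, ib)) / tot
}

#' Pairwise Dice matrix across subjects
#'
#' @param maps list of per-subject binary maps (logical arrays or index
#'   vectors).
#' @return symmetric subject x subject matrix with unit diagonal.
#' @export
pairwiseDice <- function(maps) {
  n <- length(maps)
  d <- diag(1, n)
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    d[i, j] <- d[j, i] <- diceCoefficient(maps[[i]], maps[[j]])
  }
  dimnames(d) <- list(names(maps), names(maps))
  d
}

## Ratio of mean within-group to mean between-group Dice from a precomputed
## matrix (upper triangle, unordered pairs).
.ratioFromDice <- function(d, groups) {
  n <- nrow(d)
  ut <- upper.tri(d)
  same <- outer(groups, groups, `==`)
  within <- d[ut & same]
  between <- d[ut & !same]
  mb <- mean(between)
  if (mb == 0) stop("between-group mean Dice is 0: R undefined")
  mean(within) / mb
}

#' Within/between Dice ratio R
#'
#' `R` = mean Dice over all within-group unordered pairs divided by mean
#' Dice over all between-group pairs. R > 1 indicates higher within-group
#' similarity, R < 1 higher between-group similarity, R close to 1 spatial
#' overlap between the groups. For the default 8/6 cohort the means run
#' over 28 + 15 within-pairs and 48 between-pairs.
#'
#' @param maps list of subject maps, or a precomputed Dice matrix from
#'   [pairwiseDice()].
#' @param groups character/factor of group labels (two levels, each with at
#'   least 2 subjects).
#' @return the ratio R (scalar).
#' @export
diceRatio <- function(maps, groups) {
  d <- if (is.matrix(maps)) maps else pairwiseDice(maps)
  groups <- as.character(groups)
  stopifnot(nrow(d) == length(groups))
  if (length(unique(groups)) != 2L || any(table(groups) < 2L))
    stop("need two groups with at least 2 subjects each")
  .ratioFromDice(d, groups)
}

#' Permutation confidence interval for R
#'
#' Shuffles the group labels (preserving group sizes), recomputes R per
#' iteration, and reports the 2.5th and 97.5th percentile bounds. Bounds
#' are the order statistics of the permutation draws at the add-one
#' positions `floor(0.025 (n+1))` and `n + 1 - floor(0.025 (n+1))` — the
#' exact finite-sample convention matching the add-one rank test used for
#' the decoding p-values, under which an exchangeable observed R falls
#' inside the interval with probability >= 95%. The observed maps are
#' declared group-specific iff the observed R falls outside this interval.
#'
#' @param maps subject maps or a Dice matrix (see [diceRatio()]).
#' @param groups group labels.
#' @param nPerm permutation iterations.
#' @param seed RNG seed (R-permutation substream).
#' @return list with `R` (observed), `ci`, `permR` (all draws), and
#'   `decision`.
#' @export
permuteR <- function(maps, groups, nPerm = 10000L, seed = 1L) {
  d <- if (is.matrix(maps)) maps else pairwiseDice(maps)
  groups <- as.character(groups)
  obs <- diceRatio(d, groups)
  permR <- .withSeed(.substreamSeed(seed, "Rperm"), {
    vapply(seq_len(nPerm),
           function(i) .ratioFromDice(d, sample(groups)),
           numeric(1))
  })
  k <- floor(0.025 * (nPerm + 1))
  srt <- sort(permR)
  ci <- srt[c(max(1L, k), min(nPerm, nPerm + 1L - k))]
  list(R = obs, ci = ci, permR = permR,
       decision = if (obs < ci[1L] || obs > ci[2L]) "group-specific maps"
                  else "no group-specific map")
}

## U statistic of group x against group y (mid-ranks for ties):
## U = #(x_i > y_j) + 0.5 #(x_i == y_j).
.uStat <- function(x, y) {
  sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
}

#' Exact Mann-Whitney U comparison of best windows
#'
#' Exact-enumeration Mann-Whitney U test (two-tailed) suitable for the small
#' group sizes here (8 and 6): the null distribution of U is built by
#' enumerating all assignments of the pooled values to the two groups, ties
#' handled by mid-ranks. The two-tailed p doubles the smaller tail
#' probability, capped at 1. Enumeration is used whenever the number of
#' assignments is at most `maxEnum`; beyond that a normal approximation
#' with tie correction is used (with a message).
#'
#' @param x,y numeric vectors (e.g. per-subject best windows, in seconds).
#' @param maxEnum enumeration limit on `choose(n, length(x))`.
#' @return list with `U` (for the `x` group) and `p` (two-tailed).
#' @examples
#' compareBestWindows(c(2, 2, 2), c(14, 14, 14))  # U = 0, p = 0.1
#' @export
compareBestWindows <- function(x, y, maxEnum = 2e5) {
  stopifnot(length(x) >= 1L, length(y) >= 1L)
  n1 <- length(x); n <- n1 + length(y)
  pool <- c(x, y)
  obsU <- .uStat(x, y)
  if (choose(n, n1) <= maxEnum) {
    idx <- combn(n, n1)
    nulls <- apply(idx, 2L, function(i) .uStat(pool[i], pool[-i]))
    pLow <- mean(nulls <= obsU)
    pHigh <- mean(nulls >= obsU)
    p <- min(1, 2 * min(pLow, pHigh))
  } else {
    message("too many assignments to enumerate; using normal approximation")
    n2 <- n - n1
    mu <- n1 * n2 / 2
    tie <- table(pool)
    sig2 <- n1 * n2 / 12 * (n + 1 - sum(tie^3 - tie) / (n * (n - 1)))
    z <- (obsU - mu) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(U = obsU, p = p)
}

#' Full valence comparison
#'
#' Combines the best-window Mann-Whitney U test and the Dice-ratio
#' permutation analysis into a [GroupComparison-class].
#'
#' @param maps list of per-subject decoding maps (best-accuracy window).
#' @param groups per-subject group labels ("wedding"/"funeral").
#' @param bestWindows per-subject best windows in seconds.
#' @param nPerm permutation iterations for the R confidence interval.
#' @param seed RNG seed.
#' @return a [GroupComparison-class].
#' @export
valenceComparison <- function(maps, groups, bestWindows,
                              nPerm = 10000L, seed = 1L) {
  groups <- as.character(groups)
  lv <- unique(groups)
  stopifnot(length(lv) == 2L, length(maps) == length(groups),
            length(bestWindows) == length(groups))
  u <- compareBestWindows(bestWindows[groups == lv[1L]],
                          bestWindows[groups == lv[2L]])
  d <- pairwiseDice(maps)
  pr <- permuteR(d, groups, nPerm = nPerm, seed = seed)
  new("GroupComparison", uStat = u$U, uP = u$p, diceMatrix = d,
      R = pr$R, ci = pr$ci, nPerm = as.integer(nPerm),
      decision = pr$decision)
}
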