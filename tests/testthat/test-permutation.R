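smallTensor <- function(seed = 5L, effectSize = 0) {
  spec <- tinySpec(nTrials = 8L, nRuns = 2L, gridShape = c(7L, 7L, 7L),
                   maskFraction = 0.6, nInformative = 30L,
                   effectSize = effectSize, seed = seed)
  buildTrialTensor(generateSubject(spec, 1))
}

test_that("the null distribution has the requested replicate structure", {
  tt <- smallTensor()
  null <- buildNull(tt, nPerWindow = 3L, seed = 9L, nTop = 40L,
                    minCluster = 5L)
  expect_equal(dim(null@values), c(3, 7))
  expect_length(nullValues(null), 21)
  ## pooled values are exactly the concatenated per-window sets
  expect_equal(nullValues(null), as.vector(null@values))

  one <- buildNull(tt, nPerWindow = 1L, seed = 9L, nTop = 40L,
                   minCluster = 5L)
  expect_length(nullValues(one), 7)

  ## seeded: identical on rerun, different under another seed
  again <- buildNull(tt, nPerWindow = 3L, seed = 9L, nTop = 40L,
                     minCluster = 5L)
  expect_identical(null@values, again@values)
  other <- buildNull(tt, nPerWindow = 3L, seed = 10L, nTop = 40L,
                     minCluster = 5L)
  expect_false(identical(null@values, other@values))
})

test_that("permuted accuracy is deterministic given the permutation", {
  tt <- smallTensor()
  perm <- rev(tt@trials$trial_type)
  a1 <- permutedAccuracy(tt, 6, permLabels = perm, nTop = 40L,
                         minCluster = 5L)
  a2 <- permutedAccuracy(tt, 6, permLabels = perm, nTop = 40L,
                         minCluster = 5L)
  expect_identical(a1, a2)
  expect_error(permutedAccuracy(tt, 6, permLabels = rep("true", 8)),
               "permutation")
})

test_that("the rank test implements the add-one formula with its edge cases", {
  null <- seq(0, 1, length.out = 700)
  expect_equal(rankTest(2, null), 1 / 701)       # above all nulls
  expect_equal(rankTest(-1, null), 1)            # below all nulls
  ## monotone non-increasing in the observed accuracy
  p <- rankTest(seq(0, 1, 0.05), null)
  expect_true(all(diff(p) <= 0))
  ## a NullDistribution object is accepted directly
  tt <- smallTensor()
  nd <- buildNull(tt, nPerWindow = 2L, seed = 3L, nTop = 40L,
                  minCluster = 5L)
  expect_equal(rankTest(0.5, nd), rankTest(0.5, nullValues(nd)))
})

test_that("rank-test p-values against their own null are valid and conservative", {
  ## draws from the null itself: P(p < alpha) <= alpha by exchangeability
  set.seed(61)
  nRep <- 600
  hits <- 0
  for (i in seq_len(nRep)) {
    vals <- sample(100, 21, replace = TRUE) / 100
    obs <- vals[1]
    hits <- hits + (rankTest(obs, vals[-1]) < 0.25)
  }
  expect_lt(hits / nRep, 0.25 + 2 * sqrt(0.25 * 0.75 / nRep))
})

test_that("p-values attach to a decoding result per window", {
  tt <- smallTensor(effectSize = 2)
  res <- decodeSubject(tt, nTop = 40L, minCluster = 5L, nBoot = 20L,
                       seed = 2)
  null <- buildNull(tt, nPerWindow = 5L, seed = 7L, nTop = 40L,
                    minCluster = 5L)
  res <- applyRankTest(res, null)
  expect_false(any(is.na(pValues(res))))
  expect_true(all(pValues(res) > 0 & pValues(res) <= 1))
  expect_equal(unname(pValues(res)), rankTest(res@accuracy, null))
})
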