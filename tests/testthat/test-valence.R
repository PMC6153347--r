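test_that("Dice coefficient: identity, disjointness, and brute-force agreement", {
  m <- array(FALSE, c(6, 6, 6)); m[1:3, 1:3, 1] <- TRUE
  expect_equal(diceCoefficient(m, m), 1)
  n <- array(FALSE, c(6, 6, 6)); n[4:6, 4:6, 6] <- TRUE
  expect_equal(diceCoefficient(m, n), 0)
  expect_equal(diceCoefficient(1:10, c(1:5, 101:105)), 0.5)
  expect_equal(diceCoefficient(integer(0), integer(0)), 0)

  set.seed(19)
  for (i in 1:10) {
    a <- sample(100, sample(3:30, 1))
    b <- sample(100, sample(3:30, 1))
    expect_equal(diceCoefficient(a, b), bruteDice(a, b))
  }
})

test_that("the Dice matrix is symmetric with unit diagonal", {
  set.seed(4)
  maps <- replicate(5, sample(200, 40), simplify = FALSE)
  d <- pairwiseDice(maps)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(1, 5))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("the ratio R is 1 for identical maps and errors on degenerate separation", {
  maps <- replicate(6, c(1:30), simplify = FALSE)
  groups <- rep(c("wedding", "funeral"), c(4, 2))
  expect_equal(diceRatio(maps, groups), 1)
  ## R is invariant to which group is labelled first
  expect_equal(diceRatio(maps, groups),
               diceRatio(maps, rev(groups)))

  ## disjoint group-specific maps: between-group mean 0 -> error
  mapsSep <- c(replicate(3, 1:20, simplify = FALSE),
               replicate(3, 101:120, simplify = FALSE))
  expect_error(diceRatio(mapsSep, rep(c("a", "b"), each = 3)),
               "undefined")
  expect_error(diceRatio(maps, rep("a", 6)), "two groups")
})

test_that("the permutation CI for R is seeded and contains degenerate cases", {
  set.seed(31)
  maps <- replicate(10, sample(300, 50), simplify = FALSE)
  groups <- rep(c("wedding", "funeral"), c(6, 4))
  pr <- permuteR(maps, groups, nPerm = 200L, seed = 5L)
  pr2 <- permuteR(maps, groups, nPerm = 200L, seed = 5L)
  expect_identical(pr$permR, pr2$permR)
  expect_length(pr$permR, 200)
  expect_true(pr$ci[1] <= pr$ci[2])

  one <- permuteR(maps, groups, nPerm = 1L, seed = 5L)
  expect_equal(one$ci, rep(one$permR, 2))
})

test_that("the exact Mann-Whitney test matches brute force and wilcox.test", {
  ## tied extremes: U = 0, two-tailed p = 2 * 1/20
  r <- compareBestWindows(c(2, 2, 2), c(14, 14, 14))
  expect_equal(r$U, 0)
  expect_equal(r$p, 0.1)
  ## identical samples: p capped at 1
  expect_equal(compareBestWindows(c(4, 8), c(4, 8))$p, 1)

  set.seed(27)
  for (i in 1:8) {
    x <- sample(seq(2, 14, 2), sample(2:4, 1), replace = TRUE)
    y <- sample(seq(2, 14, 2), sample(2:4, 1), replace = TRUE)
    mine <- compareBestWindows(x, y)
    ref <- bruteMannWhitney(x, y)
    expect_equal(mine$U, ref$U)
    expect_equal(mine$p, ref$p)
  }
  ## tie-free data agrees with the exact wilcox.test
  for (i in 1:5) {
    x <- sample(1000, 5); y <- sample(2000, 4) + 0.5
    w <- wilcox.test(x, y, exact = TRUE)
    mine <- compareBestWindows(x, y)
    expect_equal(mine$U, unname(w$statistic))
    expect_equal(mine$p, w$p.value)
  }
})

test_that("the full valence comparison assembles a coherent result", {
  set.seed(8)
  maps <- replicate(8, sample(400, 60), simplify = FALSE)
  groups <- rep(c("wedding", "funeral"), each = 4)
  bw <- sample(seq(2, 14, 2), 8, replace = TRUE)
  gc <- valenceComparison(maps, groups, bw, nPerm = 300L, seed = 6L)
  expect_s4_class(gc, "GroupComparison")
  expect_true(validObject(gc))
  expect_equal(dim(diceMatrix(gc)), c(8, 8))
  expect_true(gc@decision %in% c("group-specific maps",
                                 "no group-specific map"))
  ## maps drawn independently of the groups: R should sit inside the CI
  expect_true(gc@R >= gc@ci[1] && gc@R <= gc@ci[2])
})
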