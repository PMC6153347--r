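## small helpers building binary maps on a common grid
dims <- c(10L, 10L, 10L)
mapWith <- function(idx) { m <- array(FALSE, dims); m[idx] <- TRUE; m }

test_that("the probability map counts subject overlap per voxel", {
  blk <- array(FALSE, dims); blk[2:6, 2:5, 3] <- TRUE  # 20 voxels
  idx <- which(blk)
  maps <- c(replicate(5, mapWith(idx), simplify = FALSE),
            replicate(9, mapWith(integer(0)), simplify = FALSE))
  pm <- buildProbabilityMap(maps)
  expect_equal(max(probMap(pm)), 5 / 14)
  expect_gt(5 / 14, 0.33)                  # 5 of 14 clears the threshold
  expect_equal(probMap(pm)[1, 1, 1], 0)

  ## identical maps across subjects -> probabilities only 0 or 1
  same <- replicate(14, mapWith(idx), simplify = FALSE)
  expect_true(all(probMap(buildProbabilityMap(same)) %in% c(0, 1)))

  ## subject order cannot matter
  pm2 <- buildProbabilityMap(rev(maps))
  expect_equal(probMap(pm), probMap(pm2))

  ## mismatched grids are an error
  bad <- c(maps[1], list(array(FALSE, c(5L, 5L, 5L))))
  expect_error(buildProbabilityMap(bad), "grids")
})

test_that("thresholding keeps prob > 0.33 voxels in clusters of >= 20", {
  blk20 <- array(FALSE, dims); blk20[2:6, 2:5, 3] <- TRUE   # 20 voxels
  blk19 <- array(FALSE, dims); blk19[2:6, 6:9, 7] <- TRUE
  blk19[2, 6, 7] <- FALSE                                   # 19 voxels
  maps <- c(replicate(6, mapWith(which(blk20 | blk19)), simplify = FALSE),
            replicate(8, mapWith(integer(0)), simplify = FALSE))
  pm <- buildProbabilityMap(maps)                           # prob 6/14 = 0.43
  thr <- thresholdMap(pm, pThresh = 0.33, minCluster = 20L)
  expect_equal(sum(thr$map), 20)                            # 19er dropped
  expect_equal(thr$clusters$size, 20)
  expect_equal(thr$clusters$peakProb, 6 / 14)

  ## probability exactly at the threshold is dropped (strict >)
  exact <- c(replicate(33, mapWith(which(blk20)), simplify = FALSE),
             replicate(67, mapWith(integer(0)), simplify = FALSE))
  pmE <- buildProbabilityMap(exact)                         # prob = 0.33
  thrE <- thresholdMap(pmE, pThresh = 0.33, minCluster = 1L)
  expect_equal(sum(thrE$map), 0)
})

test_that("with 14 subjects the smallest count clearing 0.33 is five", {
  blk <- array(FALSE, dims); blk[1:5, 1:4, 5] <- TRUE       # 20 voxels
  idx <- which(blk)
  for (k in 1:14) {
    maps <- c(replicate(k, mapWith(idx), simplify = FALSE),
              replicate(14 - k, mapWith(integer(0)), simplify = FALSE))
    thr <- thresholdMap(buildProbabilityMap(maps), pThresh = 0.33,
                        minCluster = 20L)
    expect_equal(sum(thr$map) > 0, k >= 5)
  }
})

test_that("suprathreshold counts are non-increasing in the threshold", {
  set.seed(41)
  counts <- sample(0:14, 500, replace = TRUE)
  byThr <- amdecode:::.countsByThreshold(counts, 14L)
  expect_length(byThr, 14)
  expect_true(all(diff(byThr) <= 0))
  expect_equal(byThr[1], sum(counts >= 1))
  expect_equal(byThr[14], sum(counts == 14))
})

test_that("the sparseness test is degenerate when all maps are identical", {
  blk <- array(FALSE, dims); blk[3:7, 3:7, 3:5] <- TRUE
  idx <- which(blk)
  subjectMaps <- replicate(6, replicate(7, idx, simplify = FALSE),
                           simplify = FALSE)
  res <- sparsenessTest(subjectMaps, observedWindows = rep(8, 6),
                        gridDim = dims, nIter = 200L, seed = 3L)
  ## no variability: every draw equals the observed map -> p = 1
  expect_true(all(res$pPerThreshold == 1))
  expect_true(all(res$nullCounts[, 1] == res$observedCounts[1]))
})

test_that("sparseness respects its structural invariants", {
  set.seed(15)
  subjectMaps <- replicate(5, replicate(7, sample(prod(dims), 60),
                                        simplify = FALSE),
                           simplify = FALSE)
  res <- sparsenessTest(subjectMaps, observedWindows = rep(c(4, 8), c(3, 2)),
                        gridDim = dims, nIter = 100L, seed = 8L)
  expect_equal(res$thresholds, (1:5) / 5)
  expect_true(all(apply(res$nullCounts, 1, function(r) all(diff(r) <= 0))))
  expect_true(all(diff(res$observedCounts) <= 0))
  ## the observed combination is one possible draw
  expect_true(all(res$pPerThreshold >= 1 / 101))
  expect_equal(dim(res$fixedWindowCounts), c(7, 5))
  ## deterministic under the seed
  res2 <- sparsenessTest(subjectMaps, observedWindows = rep(c(4, 8), c(3, 2)),
                         gridDim = dims, nIter = 100L, seed = 8L)
  expect_identical(res$nullCounts, res2$nullCounts)
})
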