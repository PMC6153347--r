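test_that("fold enumeration covers all true x false pairs with full training sets", {
  labels <- rep(c("true", "false"), each = 24)
  folds <- enumerateFolds(labels)
  expect_equal(nrow(folds), 576)
  k <- 100
  train <- setdiff(seq_along(labels), folds[k, ])
  expect_length(train, 46)
  expect_equal(sum(labels[train] == "true"), 23)

  expect_equal(nrow(enumerateFolds(c("true", "true", "false", "false"))), 4)
  expect_error(enumerateFolds(c("true", "false", "false")), "at least 2")
})

test_that("fold enumeration matches the brute-force double loop", {
  set.seed(5)
  for (nt in 2:6) for (nf in 2:6) {
    labels <- sample(c(rep("true", nt), rep("false", nf)))
    expect_equal(unname(enumerateFolds(labels)),
                 unname(bruteFolds(labels)))
  }
})

test_that("the encoding model recovers a perfectly separating voxel", {
  labels <- rep(c("true", "false"), 5)
  d <- 1.7
  Y <- cbind(ifelse(labels == "true", d, -d),   # perfect separation
             rep(2, 10),                        # constant
             ifelse(labels == "true", 3 + d, 3 - d))  # offset + separation
  m <- fitEncoding(Y, labels)
  expect_equal(m@weights, c(d, 0, d))
  expect_equal(m@intercepts, c(0, 2, 3))
  expect_equal(m@r2, c(1, 0, 1))
})

test_that("encoding-model R2 under pure noise follows the Beta(1/2,(n-2)/2) null", {
  set.seed(77)
  n <- 20
  labels <- rep(c("true", "false"), each = n / 2)
  Y <- matrix(rnorm(n * 4000), n, 4000)
  m <- fitEncoding(Y, labels)
  ks <- suppressWarnings(stats::ks.test(m@r2, stats::pbeta,
                                        1 / 2, (n - 2) / 2))
  expect_gt(ks$p.value, 0.01)
  expect_equal(mean(m@r2), 1 / (n - 1), tolerance = 0.05)
})

test_that("voxel selection keeps the top set and drops small clusters", {
  dims <- c(12L, 12L, 12L)
  ## a solid 5x5x5 blob (125 voxels) of high r2 in a sea of low r2
  grid <- array(FALSE, dims)
  grid[4:8, 4:8, 4:8] <- TRUE
  blob <- which(grid)
  vox <- seq_len(prod(dims))
  set.seed(11)
  r2 <- runif(length(vox), 0, 0.2)
  r2[blob] <- runif(length(blob), 0.6, 1)
  m <- new("EncodingModel", weights = numeric(length(vox)),
           intercepts = numeric(length(vox)), r2 = r2,
           voxelIndex = as.integer(vox), gridDim = dims)
  sel <- suppressMessages(selectVoxels(m, nTop = 100L, minCluster = 21L))
  expect_length(selectedVoxels(sel), 100)
  expect_true(all(selectedVoxels(sel) %in% blob))
  expect_equal(nrow(sel@clusters), 1)

  ## scattered singletons only -> empty selection
  iso <- seq(1, prod(dims), by = 5)[1:50]   # pairwise non-adjacent
  r2b <- numeric(length(vox)); r2b[iso] <- 1
  mb <- new("EncodingModel", weights = numeric(length(vox)),
            intercepts = numeric(length(vox)), r2 = r2b,
            voxelIndex = as.integer(vox), gridDim = dims)
  selb <- suppressMessages(selectVoxels(mb, nTop = 50L, minCluster = 21L))
  expect_length(selectedVoxels(selb), 0)

  ## a 30-voxel and a 15-voxel cluster in the top set -> only the 30 kept
  g30 <- array(FALSE, dims); g30[1:5, 1:3, 1:2] <- TRUE
  g15 <- array(FALSE, dims); g15[9:11, 5:9, 12] <- TRUE       # 3x5x1
  r2c <- numeric(length(vox))
  r2c[which(g30)] <- 0.9; r2c[which(g15)] <- 0.8
  mc <- new("EncodingModel", weights = numeric(length(vox)),
            intercepts = numeric(length(vox)), r2 = r2c,
            voxelIndex = as.integer(vox), gridDim = dims)
  selc <- suppressMessages(selectVoxels(mc, nTop = 45L, minCluster = 21L))
  expect_setequal(selectedVoxels(selc), which(g30))
})

test_that("cluster labelling and filtering match the brute-force BFS oracle", {
  set.seed(21)
  dims <- c(5L, 5L, 4L)
  for (conn in c(6L, 18L, 26L)) for (rep in 1:5) {
    idx <- sort(sample(prod(dims), 40))
    expect_true(samePartition(clusterLabels(idx, dims, conn),
                              bruteComponents(idx, dims, conn)))
    expect_equal(sort(amdecode:::.clusterFilter(idx, dims, 4L, conn)),
                 sort(bruteClusterFilter(idx, dims, 4L, conn)))
  }
})

test_that("pattern prediction follows the linear model algebra", {
  labels <- rep(c("true", "false"), each = 4)
  d <- 0.8
  Y <- matrix(ifelse(labels == "true", d, -d), 8, 30) +
    matrix(rep(seq(0.1, 3, length.out = 30), each = 8), 8, 30)
  m <- fitEncoding(Y, labels, voxelIndex = 1:30, gridDim = c(30L, 1L, 1L))
  sel <- suppressMessages(selectVoxels(m, nTop = 30L, minCluster = 1L))
  pT <- predictPattern(m, sel, "true")
  pF <- predictPattern(m, sel, "false")
  expect_equal(pT - pF, 2 * m@weights[match(selectedVoxels(sel), 1:30)])
  expect_equal(pT, Y[1, match(selectedVoxels(sel), 1:30)])
})

test_that("cosine matching scores veridical, swapped and tied assignments", {
  a <- c(1, 0, 0); b <- c(0, 1, 0)
  expect_true(matchPair(a, b, a, b))       # veridical, orthogonal
  expect_false(matchPair(a, b, b, a))      # swapped
  expect_false(matchPair(a, a, a, b))      # identical predictions: tie
  expect_false(matchPair(c(0, 0), c(0, 0), a[1:2], b[1:2]))  # zero norm
})

test_that("decoding accuracy is scale-invariant and label-swap antisymmetric", {
  spec <- tinySpec(nTrials = 12L, nRuns = 2L, gridShape = c(7L, 7L, 7L),
                   maskFraction = 0.6, nInformative = 30L, effectSize = 1)
  tt <- buildTrialTensor(generateSubject(spec, 1))
  r <- decodeWindow(tt, 8, nTop = 40L, minCluster = 5L)
  expect_equal(r$accuracy, mean(r$outcomes))
  expect_equal(nrow(enumerateFolds(tt@trials$trial_type)),
               length(r$outcomes))

  ## common positive rescaling leaves every outcome unchanged
  tt2 <- tt; tt2@values <- tt@values * 7.3
  r2 <- decodeWindow(tt2, 8, nTop = 40L, minCluster = 5L)
  expect_identical(r$outcomes, r2$outcomes)

  ## training with flipped labels (folds and test assignment unchanged)
  ## reverses every fold decision: accuracy maps to 1 - accuracy
  ## (no ties or empty selections with the cluster filter disabled)
  rNF <- decodeWindow(tt, 8, nTop = 40L, minCluster = 1L)
  labs <- tt@trials$trial_type
  x <- ifelse(labs == "true", 1, -1)
  Y <- tt@values[, , 4]
  folds <- enumerateFolds(labs)
  core <- function(xt) mean(amdecode:::.decodeCore(
    Y, xt, folds, tt@voxelIndex, tt@gridDim, 40L, 1L, 6L))
  expect_equal(core(x), rNF$accuracy)
  expect_equal(core(-x), 1 - rNF$accuracy)

  ## relabelling every trial consistently (folds, training and test all
  ## flipped) is a pure symmetry: the accuracy is unchanged
  flipped <- ifelse(labs == "true", "false", "true")
  a3 <- permutedAccuracy(tt, 8, permLabels = flipped,
                         nTop = 40L, minCluster = 1L)
  expect_equal(a3, rNF$accuracy)
})

test_that("bootstrap SE matches the binomial closed form and is seeded", {
  expect_equal(bootstrapSE(rep(1L, 100), seed = 4), 0)
  set.seed(9)
  outcomes <- rbinom(576, 1, 0.5)
  se <- bootstrapSE(outcomes, nBoot = 2000L, seed = 12)
  phat <- mean(outcomes)
  expect_equal(se, sqrt(phat * (1 - phat) / 576), tolerance = 0.2)
  expect_identical(se, bootstrapSE(outcomes, nBoot = 2000L, seed = 12))
})

test_that("best-window selection takes the argmax with earliest-window ties", {
  expect_equal(pickBestWindow(c(0.5, 0.6, 0.7, 0.9, 0.7, 0.6, 0.5)), 8)
  expect_equal(pickBestWindow(rep(0.5, 7)), 2)
  expect_equal(pickBestWindow(c(0.5, 0.8, 0.6, 0.8, 0.5, 0.5, 0.5)), 4)
})

test_that("decodeSubject assembles a valid result across the seven windows", {
  spec <- tinySpec(nTrials = 8L, nRuns = 2L, gridShape = c(7L, 7L, 7L),
                   maskFraction = 0.6, nInformative = 30L)
  tt <- buildTrialTensor(generateSubject(spec, 1))
  res <- decodeSubject(tt, nTop = 40L, minCluster = 5L, nBoot = 50L,
                       seed = 2, subject = "s1")
  expect_s4_class(res, "DecodingResult")
  expect_true(validObject(res))
  expect_true(all(accuracy(res) >= 0 & accuracy(res) <= 1))
  expect_true(all(lengths(res@maps) <= 40))
  expect_true(all(is.na(pValues(res))))
})
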