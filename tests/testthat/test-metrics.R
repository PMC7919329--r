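test_that("confusion counts match their definitions", {
  ones <- matrix(1, 2, 2)
  cc <- confusionCounts(ones, ones)
  expect_equal(c(cc@TP, cc@TN, cc@FP, cc@FN), c(4, 0, 0, 0))

  truth <- matrix(0, 4, 4); truth[1:3] <- 1
  cc <- confusionCounts(matrix(0, 4, 4), truth)
  expect_equal(c(cc@FN, cc@TN), c(3, 13))
  expect_error(confusionCounts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "binary")
})

test_that("metric values follow the count formulas and identities", {
  cc <- new("ConfusionCounts", TP = 2, TN = 10, FP = 1, FN = 1)
  expect_equal(dsc(cc), 2 * 2 / 6)
  expect_equal(jsc(cc), 2 / 4)
  expect_equal(pixelAccuracy(cc), 12 / 14)
  expect_equal(svdScore(dsc(cc)), 1 - 2 / 3)

  set.seed(71)
  for (i in 1:10) {
    cc <- new("ConfusionCounts", TP = sample(0:20, 1), TN = sample(0:20, 1),
              FP = sample(0:20, 1), FN = sample(0:20, 1))
    d <- dsc(cc)
    expect_equal(jsc(cc), d / (2 - d), tolerance = 1e-12)
    expect_equal(svdScore(d), 1 - d)
    expect_gte(d, jsc(cc))
    if (!d %in% c(0, 1)) expect_gt(d, jsc(cc))
  }
  expect_error(svdScore(1.2), "0, 1")
})

test_that("perfect, disjoint and empty-empty cases hit the boundaries", {
  m <- randomMask(5, 5, 0.4)
  expect_equal(dsc(confusionCounts(m, m)), 1)
  a <- matrix(0, 2, 2); a[1] <- 1
  b <- matrix(0, 2, 2); b[4] <- 1
  expect_equal(dsc(confusionCounts(a, b)), 0)
  z <- matrix(0, 3, 3)
  expect_equal(dsc(confusionCounts(z, z)), 1)   # empty-empty convention
  expect_equal(jsc(confusionCounts(z, z)), 1)
  expect_equal(pixelAccuracy(confusionCounts(a, 1 - a)), 0)
})

test_that("vectorized counts equal the double-loop oracle", {
  set.seed(73)
  for (i in 1:5) {
    p <- randomMask(64, 64, runif(1, 0.1, 0.6))
    t <- randomMask(64, 64, runif(1, 0.1, 0.6))
    cc <- confusionCounts(p, t)
    ref <- loopConfusion(p, t)
    expect_identical(c(TP = cc@TP, TN = cc@TN, FP = cc@FP, FN = cc@FN),
                     ref + 0)
  }
})

test_that("overlap metrics are symmetric in prediction and truth", {
  set.seed(75)
  p <- randomMask(16, 16); t <- randomMask(16, 16)
  a <- confusionCounts(p, t); b <- confusionCounts(t, p)
  expect_equal(dsc(a), dsc(b))
  expect_equal(jsc(a), jsc(b))
  expect_equal(pixelAccuracy(a), pixelAccuracy(b))
})

test_that("per-slice mean and pooled aggregation differ when they should", {
  # slice 1: tiny mask, poorly segmented; slice 2: large mask, perfect
  t1 <- matrix(0, 8, 8); t1[1:2] <- 1
  p1 <- matrix(0, 8, 8); p1[3:4] <- 1        # disjoint: DSC 0
  t2 <- matrix(0, 8, 8); t2[1:40] <- 1
  pred <- array(c(p1, t2), c(8, 8, 2))
  truth <- array(c(t1, t2), c(8, 8, 2))
  perMean <- evaluateMasks(pred, truth, "per-slice-mean")
  pooled <- evaluateMasks(pred, truth, "pooled")
  expect_equal(perMean$dsc, 0.5)
  expect_gt(pooled$dsc, perMean$dsc)
  expect_equal(perMean$svd, 1 - perMean$dsc, tolerance = 1e-12)
  expect_equal(perMean$nSlices, 2)
  expect_equal(perMean$dscSe, perMean$dscSd / sqrt(2))
})

test_that("overlap renderings color FN cyan and FP magenta", {
  set.seed(77)
  bg <- matrix(runif(64, 0.2, 0.8), 8, 8)
  t <- randomMask(8, 8, 0.3)
  same <- overlapImage(t, t, bg)
  cyan <- same[, , 1] == 0 & same[, , 2] == 1 & same[, , 3] == 1
  magenta <- same[, , 1] == 1 & same[, , 2] == 0 & same[, , 3] == 1
  expect_equal(sum(cyan) + sum(magenta), 0)

  miss <- overlapImage(matrix(0, 8, 8), t, bg)
  cyan <- miss[, , 1] == 0 & miss[, , 2] == 1 & miss[, , 3] == 1
  expect_equal(sum(cyan), sum(t))

  p <- randomMask(8, 8, 0.3)
  ov <- overlapImage(p, t, bg)
  cc <- confusionCounts(p, t)
  cyan <- ov[, , 1] == 0 & ov[, , 2] == 1 & ov[, , 3] == 1
  magenta <- ov[, , 1] == 1 & ov[, , 2] == 0 & ov[, , 3] == 1
  expect_equal(sum(cyan), cc@FN)
  expect_equal(sum(magenta), cc@FP)
})
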