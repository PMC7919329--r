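smallVolume <- function(n = 6, size = 16, seed = 5) {
  generateVolume(phantomConfig(imageSize = size, tumorProbability = 1),
                 n, seed = seed)
}

test_that("experiments pair the documented inputs, targets and losses", {
  vol <- smallVolume()
  liv <- makeExperiment(vol, "liver")
  expect_equal(liv$loss, "weighted_dice")
  expect_identical(liv$masks, liverMasks(vol))

  tfl <- makeExperiment(vol, "tumor_from_liver")
  expect_equal(tfl$loss, "weighted_dice")
  expect_identical(tfl$images, imageStack(vol) * liverMasks(vol))
  expect_true(all(tfl$images[liverMasks(vol) == 0] == 0))

  tfa <- makeExperiment(vol, "tumor_from_abdomen")
  expect_equal(tfa$loss, "bce")
  expect_identical(tfa$images, imageStack(vol))
  expect_identical(tfa$masks, tumorMasks(vol))
})

test_that("the train/validation split is disjoint, exhaustive and seeded", {
  sp <- splitTrainVal(10, 0.3, seed = 1)
  expect_equal(length(sp$val), 3)
  expect_equal(length(sp$train), 7)
  expect_identical(sort(c(sp$train, sp$val)), 1:10)
  expect_identical(sp, splitTrainVal(10, 0.3, seed = 1))
  expect_false(identical(sp, splitTrainVal(10, 0.3, seed = 2)))
  expect_error(splitTrainVal(1, 0.3), "at least 2")
})

test_that("zero epochs return the untrained model and empty history", {
  set.seed(95)
  vol <- smallVolume()
  m <- buildModel(architectureConfig(depth = 2L, baseFilters = 2L,
                                     inputSize = 16L))
  before <- modelParameters(m)
  fit <- trainModel(m, imageStack(vol), liverMasks(vol),
                    trainConfig(epochs = 0, batchSize = 4))
  expect_equal(nrow(fit$history), 0)
  expect_identical(modelParameters(fit$model), before)
})

test_that("prediction thresholds behave at their extremes", {
  set.seed(97)
  m <- buildModel(architectureConfig(depth = 2L, baseFilters = 2L,
                                     inputSize = 16L))
  img <- matrix(runif(256), 16, 16)
  expect_true(all(predictMask(m, img, threshold = 0) == 1))
  expect_true(all(predictMask(m, img, threshold = 1) == 0))
})

test_that("a seeded run reproduces split, stream and history exactly", {
  vol <- smallVolume(n = 6)
  arch <- architectureConfig(depth = 2L, baseFilters = 2L, inputSize = 16L)
  tc <- trainConfig(epochs = 2, batchSize = 3, seed = 33)
  run <- function() {
    set.seed(101)
    m <- buildModel(arch)
    trainModel(m, imageStack(vol), liverMasks(vol), tc,
               augmentation = augmentationConfig())$history
  }
  expect_identical(run(), run())
})

test_that("degenerate augmentation equals the unaugmented pipeline", {
  vol <- smallVolume(n = 4)
  arch <- architectureConfig(depth = 2L, baseFilters = 2L, inputSize = 16L)
  tc <- trainConfig(epochs = 2, batchSize = 4, seed = 35)
  runWith <- function(aug) {
    set.seed(103)
    m <- buildModel(arch)
    trainModel(m, imageStack(vol), liverMasks(vol), tc,
               augmentation = aug)$history
  }
  identityAug <- augmentationConfig(rotationRange = 0, shiftRange = 0,
                                    zoomRange = c(1, 1), shearRange = 0,
                                    horizontalFlip = FALSE)
  expect_identical(runWith(NULL), runWith(identityAug))
})

test_that("optimization reduces the training loss on a small phantom set", {
  vol <- smallVolume(n = 4, size = 32, seed = 7)
  set.seed(105)
  m <- buildModel(architectureConfig(depth = 2L, baseFilters = 4L,
                                     inputSize = 32L))
  fit <- trainModel(m, imageStack(vol), liverMasks(vol),
                    trainConfig(epochs = 12, batchSize = 4,
                                learningRate = 5e-3, seed = 9))
  h <- fit$history$trainLoss
  expect_lt(mean(tail(h, 3)), mean(head(h, 3)))
  expect_gt(tail(fit$history$trainDsc, 1), head(fit$history$trainDsc, 1))
})

test_that("the cross-entropy route trains and logs finite losses", {
  vol <- smallVolume(n = 4, size = 16, seed = 13)
  set.seed(107)
  m <- buildModel(architectureConfig(depth = 2L, baseFilters = 2L,
                                     inputSize = 16L))
  fit <- trainModel(m, imageStack(vol), tumorMasks(vol),
                    trainConfig(epochs = 3, batchSize = 4, loss = "bce",
                                learningRate = 1e-3, seed = 15))
  expect_true(all(is.finite(fit$history$trainLoss)))
  expect_true(all(fit$history$trainLoss >= 0))
  expect_lt(fit$history$trainLoss[3], fit$history$trainLoss[1])
})

test_that("oversized batches are rejected", {
  vol <- smallVolume(n = 4)
  m <- buildModel(architectureConfig(depth = 2L, baseFilters = 2L,
                                     inputSize = 16L))
  expect_error(trainModel(m, imageStack(vol), liverMasks(vol),
                          trainConfig(batchSize = 16)), "exceeds")
})
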