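test_that("degenerate ranges sample identity parameters", {
  cfg <- augmentationConfig(rotationRange = 0, shiftRange = 0,
                            zoomRange = c(1, 1), shearRange = 0,
                            horizontalFlip = FALSE)
  set.seed(41)
  p <- sampleTransform(cfg)
  expect_equal(p, list(angle = 0, shiftX = 0, shiftY = 0, zoom = 1,
                       shear = 0, flip = FALSE))
})

test_that("sampled parameters respect their ranges and are uniform", {
  cfg <- augmentationConfig(rotationRange = 10, shiftRange = 0.05,
                            zoomRange = c(0.9, 1.1), shearRange = 5)
  set.seed(43)
  draws <- replicate(1e4, unlist(sampleTransform(cfg)))
  expect_true(all(abs(draws["angle", ]) <= 10))
  expect_true(all(abs(draws["shiftX", ]) <= 0.05))
  expect_true(all(draws["zoom", ] >= 0.9 & draws["zoom", ] <= 1.1))
  expect_true(all(abs(draws["shear", ]) <= 5))
  # uniform means: midpoint within 3 standard errors
  se <- function(a, b) (b - a) / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(draws["angle", ]) - 0), 3 * se(-10, 10))
  expect_lt(abs(mean(draws["zoom", ]) - 1), 3 * se(0.9, 1.1))
  expect_lt(abs(mean(draws["flip", ]) - 0.5), 3 * 0.5 / sqrt(1e4))
})

test_that("identity parameters return the input bit-identically", {
  set.seed(45)
  img <- matrix(runif(256), 16, 16)
  msk <- randomMask(16, 16)
  tr <- applyTransform(img, msk, livseg:::identityTransform())
  expect_identical(tr$image, img)
  expect_identical(tr$mask, msk)
})

test_that("rotations move a single pixel to its closed-form coordinate", {
  # pixel centers sit at i - 1/2; rotation by a about the center (S/2,
  # S/2) maps pixel p to round(R_a (p - 1/2 - c) + c + 1/2)
  S <- 16
  msk <- matrix(0, S, S); msk[4, 7] <- 1
  for (ang in c(90, 45, -30)) {
    tr <- applyTransform(msk, msk, list(angle = ang, shiftX = 0,
                                        shiftY = 0, zoom = 1, shear = 0,
                                        flip = FALSE))
    a <- ang * pi / 180
    rel <- c(4 - 0.5 - S / 2, 7 - 0.5 - S / 2)
    rot <- c(cos(a) * rel[1] - sin(a) * rel[2],
             sin(a) * rel[1] + cos(a) * rel[2])
    px <- round(rot + S / 2 + 0.5)
    expect_equal(which(tr$mask == 1),
                 (px[2] - 1) * S + px[1],
                 info = paste("angle", ang))
  }
})

test_that("a horizontal flip mirrors the column index", {
  S <- 16
  msk <- matrix(0, S, S); msk[4, 7] <- 1
  tr <- applyTransform(msk, msk, list(angle = 0, shiftX = 0, shiftY = 0,
                                      zoom = 1, shear = 0, flip = TRUE))
  expect_equal(which(tr$mask == 1), (S + 1 - 7 - 1) * S + 4)
})

test_that("random transforms keep masks binary with bounded area change", {
  set.seed(47)
  sl <- generateSlice(phantomConfig(imageSize = 64, tumorProbability = 0))
  cfg <- augmentationConfig()
  for (i in 1:10) {
    p <- sampleTransform(cfg)
    tr <- applyTransform(sl$image, sl$liverMask, p)
    expect_true(all(tr$mask %in% c(0, 1)))
    expect_identical(dim(tr$image), dim(sl$image))
    # area scales like zoom^2 up to interpolation edge effects
    expect_lt(abs(sum(tr$mask) - p$zoom^2 * sum(sl$liverMask)),
              0.15 * sum(sl$liverMask))
  }
})

test_that("image and mask transform consistently on a synthetic disk", {
  S <- 64
  X <- matrix(seq_len(S), S, S); Y <- t(X)
  disk <- ((X - 30)^2 + (Y - 38)^2 <= 12^2) * 1
  set.seed(49)
  cfg <- augmentationConfig()
  for (i in 1:5) {
    tr <- applyTransform(disk, disk, sampleTransform(cfg))
    rebin <- (tr$image > 0.5) * 1   # bilinear image, re-thresholded
    disagree <- which(rebin != tr$mask, arr.ind = TRUE)
    # any disagreement must sit on the mask boundary (mixed 3x3 patch)
    for (r in seq_len(nrow(disagree))) {
      i0 <- disagree[r, 1]; j0 <- disagree[r, 2]
      patch <- tr$mask[max(1, i0 - 1):min(S, i0 + 1),
                       max(1, j0 - 1):min(S, j0 + 1)]
      expect_true(any(patch == 0) && any(patch == 1))
    }
  }
})

test_that("a seeded augmentation stream is reproducible", {
  cfg <- augmentationConfig()
  set.seed(51); a <- replicate(20, unlist(sampleTransform(cfg)))
  set.seed(51); b <- replicate(20, unlist(sampleTransform(cfg)))
  expect_identical(a, b)
})

test_that("nearest-edge filling replicates border intensities", {
  img <- matrix(0.8, 16, 16)  # constant image: no zeros may appear
  p <- list(angle = 25, shiftX = 0.1, shiftY = -0.1, zoom = 1, shear = 0,
            flip = FALSE)
  trZero <- applyTransform(img, NULL, p, fillMode = "constant-zero")
  trEdge <- applyTransform(img, NULL, p, fillMode = "nearest-edge")
  expect_true(any(trZero$image == 0))
  expect_true(all(trEdge$image == 0.8))
})

test_that("invalid augmentation configurations are rejected", {
  expect_error(augmentationConfig(zoomRange = c(1.1, 1.2)), "contain 1")
  expect_error(augmentationConfig(rotationRange = -1))
})
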