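test_that("mask merging is a pixel-wise union", {
  a <- matrix(0, 2, 2); a[1, 1] <- 1
  b <- matrix(0, 2, 2); b[2, 2] <- 1
  expect_equal(mergeMasks(list(a, b)), pmax(a, b))
  expect_equal(mergeMasks(list(a, a)), a)  # idempotent
  expect_error(mergeMasks(list(a, matrix(0, 3, 3))), "different shape")
  expect_error(mergeMasks(list(matrix(0.5, 2, 2))), "not binary")

  set.seed(21)
  masks <- lapply(1:7, function(i) randomMask(9, 11, 0.15))
  merged <- mergeMasks(masks)
  anySet <- Reduce(`+`, masks) >= 1
  expect_equal(sum(merged), sum(anySet))
  expect_true(all((merged == 1) == anySet))
})

test_that("combined {0,1,2} labels split into nested binary masks", {
  z <- array(0L, c(2, 2, 2))
  sp <- splitCombinedLabels(z)
  expect_true(all(sp$liver == 0) && all(sp$tumor == 0))

  lab <- matrix(c(0, 2, 1, 0), 2)  # [[0,1],[2,0]] in row order
  sp <- splitCombinedLabels(lab)
  expect_equal(sp$liver, matrix(c(0, 1, 1, 0), 2))
  expect_equal(sp$tumor, matrix(c(0, 1, 0, 0), 2))

  set.seed(23)
  lab <- array(sample(0:2, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
  sp <- splitCombinedLabels(lab)
  expect_true(all(sp$tumor <= sp$liver))
  expect_identical(combineLabels(sp$liver, sp$tumor),
                   array(as.numeric(lab), dim(lab)))

  expect_error(splitCombinedLabels(matrix(c(0, 3, 1, 2), 2)), "3")
})

test_that("the slice filter keeps exactly the foreground-carrying slices", {
  size <- 16
  counts <- c(0, 5, 0, 12)
  lv <- array(0, c(size, size, 4))
  for (i in seq_along(counts)) if (counts[i] > 0)
    lv[seq_len(counts[i]), 1, i] <- 1
  vol <- VolumePair(array(0.5, dim(lv)), lv, array(0, dim(lv)))
  fl <- filterSlices(vol, "liver")
  expect_identical(fl$kept, c(2L, 4L))
  expect_equal(fl$report$nRemoved, 2)
  expect_equal(fl$report$nKept + fl$report$nRemoved, fl$report$nTotal)
  expect_gt(fl$report$ratioAfter, fl$report$ratioBefore)

  empty <- VolumePair(array(0.5, dim(lv)), array(0, dim(lv)),
                      array(0, dim(lv)))
  fe <- filterSlices(empty, "liver")
  expect_identical(fe$kept, integer(0))
  expect_equal(fe$report$ratioAfter, 0)
})

test_that("filtering a margin volume removes the empty margins only", {
  vol <- generateVolume(phantomConfig(imageSize = 24), 10,
                        emptyMargin = 0.2, seed = 29)
  fl <- filterSlices(vol, "liver")
  expect_equal(fl$report$nRemoved, 4)
  expect_identical(fl$kept, 3:8)
  expect_gt(fl$report$ratioAfter, fl$report$ratioBefore)
})

test_that("pixel ratio equals the foreground/background quotient", {
  m <- matrix(0, 10, 10); m[1:10] <- 1
  expect_equal(pixelRatio(m), 10 / 90)
  expect_equal(pixelRatio(matrix(0, 4, 4)), 0)
  expect_error(pixelRatio(matrix(1, 2, 2)), "no background")
  expect_error(pixelRatio(matrix(0.5, 2, 2)), "binary")

  set.seed(31)
  r <- randomMask(13, 17, 0.4)
  fg <- 0; bg <- 0
  for (i in 1:13) for (j in 1:17)
    if (r[i, j] == 1) fg <- fg + 1 else bg <- bg + 1
  expect_equal(pixelRatio(r), fg / bg)
})

test_that("preprocessing resizes with the 0.25 factor to 128 pixels", {
  set.seed(33)
  img <- matrix(runif(512 * 512), 512, 512)
  msk <- randomMask(512, 512, 0.2)
  p <- preprocessSlice(img, msk, scale = 0.25)
  expect_identical(dim(p$image), c(128L, 128L))
  expect_identical(dim(p$mask), c(128L, 128L))
  expect_equal(range(p$image), c(0, 1))
  expect_true(all(p$mask %in% c(0, 1)))
})

test_that("preprocessing is identity at scale 1 on a normalized image", {
  img <- matrix(seq(0, 1, length.out = 36), 6, 6)
  p <- preprocessSlice(img, NULL, scale = 1)
  expect_equal(p$image, img)
})

test_that("mask resizing preserves binarity and output shape is floored", {
  set.seed(35)
  for (i in 1:5) {
    h <- sample(20:40, 1); w <- sample(20:40, 1); s <- runif(1, 0.3, 0.9)
    p <- preprocessSlice(matrix(runif(h * w), h, w), randomMask(h, w), s)
    expect_identical(dim(p$image),
                     as.integer(c(floor(h * s), floor(w * s))))
    expect_true(all(p$mask %in% c(0, 1)))
  }
})

test_that("a constant image normalizes to zeros with a warning", {
  expect_warning(p <- preprocessSlice(matrix(0.7, 8, 8), NULL, 0.5),
                 "constant")
  expect_true(all(p$image == 0))
})
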