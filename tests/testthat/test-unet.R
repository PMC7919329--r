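test_that("configuration enforces the divisibility needed by the skips", {
  expect_error(architectureConfig(inputSize = 100), "divisible")
  expect_silent(architectureConfig(inputSize = 96, depth = 4L))
  expect_error(architectureConfig(kernelSize = 4L))
  cfg <- architectureConfig()
  expect_identical(encoderSizes(cfg), c(128L, 64L, 32L, 16L, 8L))
  expect_identical(livseg:::encoderFilters(cfg), c(16, 32, 64, 128))
  expect_identical(livseg:::bottleneckFilters(cfg), 256)
  expect_identical(
    livseg:::bottleneckFilters(architectureConfig(bottleneck = "same")),
    128)
})

test_that("forward pass preserves spatial shape with outputs in (0, 1)", {
  set.seed(81)
  for (s in c(16L, 32L)) {
    m <- buildModel(architectureConfig(depth = 2L, baseFilters = 2L,
                                       inputSize = s))
    x <- array(runif(s * s * 2), c(s, s, 1L, 2L))
    p <- livseg:::unetForward(m, x, training = FALSE)$prob
    expect_identical(dim(p), c(s, s, 1L, 2L))
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("parameter count equals the layer-by-layer census", {
  set.seed(83)
  m <- buildModel(architectureConfig())
  expect_equal(countParameters(m), censusParameters(4, 16))
  m2 <- buildModel(architectureConfig(depth = 3L, baseFilters = 8L,
                                      inputSize = 64L))
  expect_equal(countParameters(m2), censusParameters(3, 8))
  m3 <- buildModel(architectureConfig(bottleneck = "same"))
  expect_equal(countParameters(m3),
               censusParameters(4, 16, bottleneckDouble = FALSE))
})

test_that("doubling the base filters multiplies parameters by about 4", {
  set.seed(85)
  small <- countParameters(buildModel(architectureConfig(baseFilters = 8L)))
  big <- countParameters(buildModel(architectureConfig(baseFilters = 16L)))
  expect_gt(big / small, 3.5)
  expect_lt(big / small, 4.3)
})

test_that("zero weights give a constant half probability map", {
  set.seed(87)
  m <- buildModel(architectureConfig(depth = 2L, baseFilters = 2L,
                                     inputSize = 16L))
  m@state$params <- lapply(m@state$params, function(p)
    lapply(p, function(a) { a[] <- 0; a }))
  x <- array(runif(16 * 16), c(16L, 16L, 1L, 1L))
  p <- livseg:::unetForward(m, x, training = FALSE)$prob
  expect_true(all(p == 0.5))
})

test_that("inference is deterministic with dropout disabled", {
  set.seed(89)
  m <- buildModel(architectureConfig(depth = 2L, baseFilters = 2L,
                                     inputSize = 16L, dropoutRate = 0))
  x <- array(runif(16 * 16 * 2), c(16L, 16L, 1L, 2L))
  p1 <- livseg:::unetForward(m, x, training = FALSE)$prob
  p2 <- livseg:::unetForward(m, x, training = FALSE)$prob
  expect_identical(p1, p2)
})

test_that("backpropagated gradients match a directional derivative", {
  set.seed(91)
  cfg <- architectureConfig(depth = 2L, baseFilters = 2L, inputSize = 8L,
                            dropoutRate = 0)
  m <- buildModel(cfg)
  x <- array(runif(8 * 8 * 2), c(8L, 8L, 1L, 2L))
  y <- array(randomMask(8, 16), c(8L, 8L, 1L, 2L))
  for (lossName in c("weighted_dice", "bce")) {
    fwd <- livseg:::unetForward(m, x, training = TRUE)
    lg <- livseg:::batchLossGrad(fwd$prob, y, lossName, 1, 0.5)
    G <- livseg:::unetBackward(m, fwd$cache, lg$dlogits)
    set.seed(92)
    dir <- lapply(m@state$params, function(p)
      lapply(p, function(a) { d <- a; d[] <- rnorm(length(a)); d }))
    nrm <- sqrt(sum(vapply(dir, function(p)
      sum(vapply(p, function(a) sum(a^2), 0)), 0)))
    dir <- lapply(dir, function(p) lapply(p, function(a) a / nrm))
    gdot <- 0
    for (nm in names(G)) {
      gv <- if (!is.null(G[[nm]]$w)) list(G[[nm]]$w, G[[nm]]$b)
            else list(G[[nm]]$gamma, G[[nm]]$beta)
      for (j in 1:2) gdot <- gdot + sum(gv[[j]] * dir[[nm]][[j]])
    }
    eps <- 1e-3
    lossAt <- function(s) {
      m2 <- m
      p <- m@state$params
      for (nm in names(p)) for (j in seq_along(p[[nm]]))
        p[[nm]][[j]] <- p[[nm]][[j]] + s * eps * dir[[nm]][[j]]
      st <- new.env(); st$params <- p; st$running <- m@state$running
      m2@state <- st
      pr <- livseg:::unetForward(m2, x, training = TRUE,
                                 keepCache = FALSE)$prob
      livseg:::batchLossGrad(pr, y, lossName, 1, 0.5)$loss
    }
    fd <- (lossAt(1) - lossAt(-1)) / (2 * eps)
    expect_equal(gdot, fd, tolerance = 0.01)
  }
})

test_that("prediction rejects inputs the pooling pyramid cannot divide", {
  set.seed(93)
  m <- buildModel(architectureConfig(depth = 2L, baseFilters = 2L,
                                     inputSize = 16L))
  expect_error(predictMask(m, matrix(runif(15 * 15), 15, 15)),
               "preprocess")
})
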