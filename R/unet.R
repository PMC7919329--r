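#' U-Net architecture configuration
#'
#' Fully determines the network: a contracting path of \code{depth}
#' blocks, each two (3x3 conv, ReLU, batch norm) units followed by 2x2 max
#' pooling and dropout; a two-convolution bottleneck; an expanding path of
#' \code{depth} blocks, each a stride-2 2x2 transposed convolution,
#' concatenation with the matching contracting-path feature map, and two
#' (conv, ReLU, BN) units; and a 1x1 convolution with a sigmoid producing
#' the per-pixel foreground probability. Filter counts start at
#' \code{baseFilters} in the first block and double per level (16, 32, 64,
#' 128 by default).
#'
#' @param depth number of encoder/decoder levels (default 4)
#' @param baseFilters filters in the first block (default 16)
#' @param kernelSize odd convolution kernel size (default 3)
#' @param poolSize pooling factor (default 2; the engine implements 2)
#' @param dropoutRate dropout after each encoder pooling step, in [0, 1)
#' @param inputSize square input side; must be divisible by
#'   \code{poolSize^depth} so skip shapes align for concatenation
#' @param inChannels,outChannels input/output channel counts (default 1)
#' @param bottleneck \code{"double"}: bottleneck width
#'   \code{baseFilters * 2^depth} (standard doubling, default);
#'   \code{"same"}: keep the last encoder width
#' @param bnOrder \code{"conv-relu-bn"} (default) or \code{"conv-bn-relu"}
#' @return a validated configuration (classed list)
#' @export
architectureConfig <- function(depth = 4L, baseFilters = 16L,
                               kernelSize = 3L, poolSize = 2L,
                               dropoutRate = 0.5, inputSize = 128L,
                               inChannels = 1L, outChannels = 1L,
                               bottleneck = c("double", "same"),
                               bnOrder = c("conv-relu-bn",
                                           "conv-bn-relu")) {
  bottleneck <- match.arg(bottleneck)
  bnOrder <- match.arg(bnOrder)
  stopifnot(depth >= 1, baseFilters >= 1, kernelSize >= 1,
            kernelSize %% 2 == 1, poolSize == 2L,
            dropoutRate >= 0, dropoutRate < 1,
            inChannels >= 1, outChannels >= 1)
  if (inputSize %% poolSize^depth != 0)
    stop(sprintf(
      "inputSize (%d) must be divisible by poolSize^depth (%d) so that ",
      inputSize, poolSize^depth),
      "encoder and decoder feature maps align for concatenation")
  cfg <- list(depth = as.integer(depth),
              baseFilters = as.integer(baseFilters),
              kernelSize = as.integer(kernelSize),
              poolSize = as.integer(poolSize),
              dropoutRate = dropoutRate,
              inputSize = as.integer(inputSize),
              inChannels = as.integer(inChannels),
              outChannels = as.integer(outChannels),
              bottleneck = bottleneck, bnOrder = bnOrder)
  class(cfg) <- "architectureConfig"
  cfg
}

encoderFilters <- function(cfg) cfg$baseFilters * 2^(seq_len(cfg$depth) - 1L)

bottleneckFilters <- function(cfg) {
  if (cfg$bottleneck == "double") cfg$baseFilters * 2^cfg$depth
  else cfg$baseFilters * 2^(cfg$depth - 1L)
}

#' Per-level spatial sizes of the encoder
#'
#' @param config an \code{\link{architectureConfig}}
#' @return integer vector of length \code{depth + 1}: input size at each
#'   encoder level and at the bottleneck (e.g. 128, 64, 32, 16, 8)
#' @export
encoderSizes <- function(config) {
  as.integer(config$inputSize / config$poolSize^(0:config$depth))
}

initConv <- function(k, cin, f) {
  list(w = array(rnorm(k * k * cin * f, sd = sqrt(2 / (k * k * cin))),
                 c(k, k, cin, f)),
       b = numeric(f))
}

initUpconv <- function(cin, f) {
  list(w = array(rnorm(4 * cin * f, sd = sqrt(2 / (4 * cin))),
                 c(2, 2, cin, f)),
       b = numeric(f))
}

initBN <- function(f) list(gamma = rep(1, f), beta = numeric(f))

#' Build a U-Net model
#'
#' Allocates and He-initializes all trainable parameters for the
#' configured architecture. Initialization draws from the R session RNG;
#' seed beforehand for reproducible weights.
#'
#' @param config an \code{\link{architectureConfig}}
#' @return a \linkS4class{UNetModel}
#' @examples
#' set.seed(1)
#' m <- buildModel(architectureConfig(inputSize = 32, baseFilters = 4))
#' countParameters(m)
#' @export
buildModel <- function(config) {
  stopifnot(inherits(config, "architectureConfig"))
  k <- config$kernelSize
  filt <- encoderFilters(config)
  params <- list()
  running <- list()
  cin <- config$inChannels
  for (i in seq_len(config$depth)) {
    f <- filt[i]
    params[[paste0("enc", i, ".conv1")]] <- initConv(k, cin, f)
    params[[paste0("enc", i, ".bn1")]] <- initBN(f)
    params[[paste0("enc", i, ".conv2")]] <- initConv(k, f, f)
    params[[paste0("enc", i, ".bn2")]] <- initBN(f)
    running[[paste0("enc", i, ".bn1")]] <- list(mean = numeric(f),
                                                var = rep(1, f))
    running[[paste0("enc", i, ".bn2")]] <- list(mean = numeric(f),
                                                var = rep(1, f))
    cin <- f
  }
  fb <- bottleneckFilters(config)
  params[["bot.conv1"]] <- initConv(k, cin, fb)
  params[["bot.bn1"]] <- initBN(fb)
  params[["bot.conv2"]] <- initConv(k, fb, fb)
  params[["bot.bn2"]] <- initBN(fb)
  running[["bot.bn1"]] <- list(mean = numeric(fb), var = rep(1, fb))
  running[["bot.bn2"]] <- list(mean = numeric(fb), var = rep(1, fb))
  cin <- fb
  for (i in rev(seq_len(config$depth))) {
    f <- filt[i]
    params[[paste0("dec", i, ".up")]] <- initUpconv(cin, f)
    params[[paste0("dec", i, ".conv1")]] <- initConv(k, 2L * f, f)
    params[[paste0("dec", i, ".bn1")]] <- initBN(f)
    params[[paste0("dec", i, ".conv2")]] <- initConv(k, f, f)
    params[[paste0("dec", i, ".bn2")]] <- initBN(f)
    running[[paste0("dec", i, ".bn1")]] <- list(mean = numeric(f),
                                                var = rep(1, f))
    running[[paste0("dec", i, ".bn2")]] <- list(mean = numeric(f),
                                                var = rep(1, f))
    cin <- f
  }
  params[["head"]] <- initConv(1L, cin, config$outChannels)
  state <- new.env(parent = emptyenv())
  state$params <- params
  state$running <- running
  new("UNetModel", config = unclass(config), state = state)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution weights and biases,
#' batch-norm scale and shift; running statistics are not trainable).
#'
#' @param model a \linkS4class{UNetModel}
#' @return non-negative integer count
#' @export
countParameters <- function(model) {
  stopifnot(is(model, "UNetModel"))
  sum(vapply(model@state$params,
             function(p) sum(vapply(p, length, 0L)), 0))
}

#' Snapshot of the model parameters
#'
#' @param model a \linkS4class{UNetModel}
#' @return named list of parameter arrays (a copy; modifying it does not
#'   affect the model)
#' @export
modelParameters <- function(model) model@state$params

## ---- layer primitives (R side glue over the C++ kernels) -----------------

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

dropoutF <- function(x, rate) {
  keep <- 1 - rate
  mask <- (runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  list(y = x * mask, mask = mask)
}

concatF <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# One conv -> ReLU -> BN unit (or conv -> BN -> ReLU when configured).
# In training mode the conv keeps its im2col matrix for the backward pass
# and batch statistics update the running estimates.
convUnitF <- function(x, pconv, pbn, run, training, bnOrder) {
  if (!training) {
    cy <- nn_conv2d_fwd(x, pconv$w, pconv$b)
    y <- if (bnOrder == "conv-relu-bn") {
      nn_bn_infer(nn_relu_fwd(cy), pbn$gamma, pbn$beta, run$mean, run$var,
                  BN_EPS)
    } else {
      nn_relu_fwd(nn_bn_infer(cy, pbn$gamma, pbn$beta, run$mean, run$var,
                              BN_EPS))
    }
    return(list(y = y, run = run, cache = NULL))
  }
  cv <- nn_conv2d_train_fwd(x, pconv$w, pconv$b)
  if (bnOrder == "conv-relu-bn") {
    r <- nn_relu_fwd(cv$y)
    bn <- nn_bn_fwd(r, pbn$gamma, pbn$beta, BN_EPS)
    y <- bn$y
    bnIn <- r
  } else {
    bn <- nn_bn_fwd(cv$y, pbn$gamma, pbn$beta, BN_EPS)
    r <- nn_relu_fwd(bn$y)
    y <- r
    bnIn <- cv$y
  }
  run$mean <- BN_MOMENTUM * run$mean + (1 - BN_MOMENTUM) * bn$mean
  run$var <- BN_MOMENTUM * run$var +
    (1 - BN_MOMENTUM) * (1 / bn$istd^2 - BN_EPS)
  list(y = y, run = run,
       cache = list(cols = cv$cols, xdim = cv$xdim, relu = r,
                    bnIn = bnIn, bnMean = bn$mean, bnIstd = bn$istd))
}

convUnitB <- function(dy, cache, pconv, pbn, bnOrder, needDx = TRUE) {
  if (bnOrder == "conv-relu-bn") {
    bb <- nn_bn_bwd(dy, cache$bnIn, cache$bnMean, cache$bnIstd, pbn$gamma)
    dr <- nn_relu_bwd(bb$dx, cache$relu)
  } else {
    dr0 <- nn_relu_bwd(dy, cache$relu)
    bb <- nn_bn_bwd(dr0, cache$bnIn, cache$bnMean, cache$bnIstd, pbn$gamma)
    dr <- bb$dx
  }
  cb <- nn_conv2d_train_bwd(cache$cols, pconv$w, dr, cache$xdim, needDx)
  list(dx = cb$dx,
       grads = list(conv = list(w = cb$dw, b = cb$db),
                    bn = list(gamma = bb$dgamma, beta = bb$dbeta)))
}

## ---- full network forward / backward -------------------------------------

# Forward pass. x: array (H, W, C, N). Returns the sigmoid probability map
# plus (optionally) every cache needed by unetBackward. Running BN stats in
# model@state are updated in place when training = TRUE.
unetForward <- function(model, x, training = FALSE, keepCache = training) {
  cfg <- model@config
  P <- model@state$params
  R <- model@state$running
  cache <- list(enc = vector("list", cfg$depth),
                dec = vector("list", cfg$depth))
  skips <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {
    id <- paste0("enc", i)
    u1 <- convUnitF(x, P[[paste0(id, ".conv1")]], P[[paste0(id, ".bn1")]],
                    R[[paste0(id, ".bn1")]], training, cfg$bnOrder)
    R[[paste0(id, ".bn1")]] <- u1$run
    u2 <- convUnitF(u1$y, P[[paste0(id, ".conv2")]],
                    P[[paste0(id, ".bn2")]], R[[paste0(id, ".bn2")]],
                    training, cfg$bnOrder)
    R[[paste0(id, ".bn2")]] <- u2$run
    skips[[i]] <- u2$y
    pl <- nn_maxpool2_fwd(u2$y)
    x <- pl$y
    drop <- NULL
    if (training && cfg$dropoutRate > 0) {
      dr <- dropoutF(x, cfg$dropoutRate)
      x <- dr$y
      drop <- dr$mask
    }
    if (keepCache)
      cache$enc[[i]] <- list(u1 = u1$cache, u2 = u2$cache,
                             argmax = pl$argmax, poolIn = dim(skips[[i]]),
                             drop = drop)
  }
  u1 <- convUnitF(x, P[["bot.conv1"]], P[["bot.bn1"]], R[["bot.bn1"]],
                  training, cfg$bnOrder)
  R[["bot.bn1"]] <- u1$run
  u2 <- convUnitF(u1$y, P[["bot.conv2"]], P[["bot.bn2"]], R[["bot.bn2"]],
                  training, cfg$bnOrder)
  R[["bot.bn2"]] <- u2$run
  x <- u2$y
  if (keepCache) cache$bot <- list(u1 = u1$cache, u2 = u2$cache)
  for (i in rev(seq_len(cfg$depth))) {
    id <- paste0("dec", i)
    up <- P[[paste0(id, ".up")]]
    upIn <- x
    x <- nn_upconv2_fwd(x, up$w, up$b)
    skip <- skips[[i]]
    if (!identical(dim(x)[1:2], dim(skip)[1:2]))
      stop(sprintf(
        "skip connection shape mismatch at level %d: upsampled %dx%d vs skip %dx%d",
        i, dim(x)[1], dim(x)[2], dim(skip)[1], dim(skip)[2]))
    cat3 <- concatF(x, skip)
    u1 <- convUnitF(cat3, P[[paste0(id, ".conv1")]],
                    P[[paste0(id, ".bn1")]], R[[paste0(id, ".bn1")]],
                    training, cfg$bnOrder)
    R[[paste0(id, ".bn1")]] <- u1$run
    u2 <- convUnitF(u1$y, P[[paste0(id, ".conv2")]],
                    P[[paste0(id, ".bn2")]], R[[paste0(id, ".bn2")]],
                    training, cfg$bnOrder)
    R[[paste0(id, ".bn2")]] <- u2$run
    if (keepCache)
      cache$dec[[i]] <- list(upIn = upIn, nUp = dim(x)[3],
                             u1 = u1$cache, u2 = u2$cache)
    x <- u2$y
  }
  if (keepCache) {
    hv <- nn_conv2d_train_fwd(x, P[["head"]]$w, P[["head"]]$b)
    logits <- hv$y
    cache$head <- list(cols = hv$cols, xdim = hv$xdim)
  } else {
    logits <- nn_conv2d_fwd(x, P[["head"]]$w, P[["head"]]$b)
  }
  prob <- 1 / (1 + exp(-logits))
  model@state$running <- R
  list(prob = prob, cache = if (keepCache) cache else NULL)
}

# Backward pass from dL/dlogits; returns gradients named like the params.
unetBackward <- function(model, cache, dlogits) {
  cfg <- model@config
  P <- model@state$params
  G <- list()
  hb <- nn_conv2d_train_bwd(cache$head$cols, P[["head"]]$w, dlogits,
                            cache$head$xdim, TRUE)
  G[["head"]] <- list(w = hb$dw, b = hb$db)
  dx <- hb$dx
  skipGrads <- vector("list", cfg$depth)
  for (i in seq_len(cfg$depth)) {   # decoder levels, shallow to deep
    id <- paste0("dec", i)
    dc <- cache$dec[[i]]
    b2 <- convUnitB(dx, dc$u2, P[[paste0(id, ".conv2")]],
                    P[[paste0(id, ".bn2")]], cfg$bnOrder)
    G[[paste0(id, ".conv2")]] <- b2$grads$conv
    G[[paste0(id, ".bn2")]] <- b2$grads$bn
    b1 <- convUnitB(b2$dx, dc$u1, P[[paste0(id, ".conv1")]],
                    P[[paste0(id, ".bn1")]], cfg$bnOrder)
    G[[paste0(id, ".conv1")]] <- b1$grads$conv
    G[[paste0(id, ".bn1")]] <- b1$grads$bn
    dcat <- b1$dx
    dup <- dcat[, , seq_len(dc$nUp), , drop = FALSE]
    skipGrads[[i]] <- dcat[, , dc$nUp + seq_len(dim(dcat)[3] - dc$nUp), ,
                           drop = FALSE]
    ub <- nn_upconv2_bwd(dc$upIn, P[[paste0(id, ".up")]]$w, dup)
    G[[paste0(id, ".up")]] <- list(w = ub$dw, b = ub$db)
    dx <- ub$dx   # gradient into the deeper decoder level / bottleneck
  }
  dBot <- dx
  b2 <- convUnitB(dBot, cache$bot$u2, P[["bot.conv2"]], P[["bot.bn2"]],
                  cfg$bnOrder)
  G[["bot.conv2"]] <- b2$grads$conv
  G[["bot.bn2"]] <- b2$grads$bn
  b1 <- convUnitB(b2$dx, cache$bot$u1, P[["bot.conv1"]], P[["bot.bn1"]],
                  cfg$bnOrder)
  G[["bot.conv1"]] <- b1$grads$conv
  G[["bot.bn1"]] <- b1$grads$bn
  dx <- b1$dx
  for (i in rev(seq_len(cfg$depth))) {  # encoder levels, deep to shallow
    id <- paste0("enc", i)
    ec <- cache$enc[[i]]
    if (!is.null(ec$drop)) dx <- dx * ec$drop
    dpool <- nn_maxpool2_bwd(dx, ec$argmax, as.integer(ec$poolIn))
    dskip <- dpool + skipGrads[[i]]
    b2 <- convUnitB(dskip, ec$u2, P[[paste0(id, ".conv2")]],
                    P[[paste0(id, ".bn2")]], cfg$bnOrder)
    G[[paste0(id, ".conv2")]] <- b2$grads$conv
    G[[paste0(id, ".bn2")]] <- b2$grads$bn
    b1 <- convUnitB(b2$dx, ec$u1, P[[paste0(id, ".conv1")]],
                    P[[paste0(id, ".bn1")]], cfg$bnOrder,
                    needDx = (i > 1L))
    G[[paste0(id, ".conv1")]] <- b1$grads$conv
    G[[paste0(id, ".bn1")]] <- b1$grads$bn
    if (i > 1L) dx <- b1$dx
  }
  G
}
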