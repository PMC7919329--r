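#' Configuration for on-the-fly affine augmentation
#'
#' Parameter ranges for the random affine deformations applied jointly to
#' an image and its mask during training. Defaults are conservative
#' (organs keep their anatomical orientation in axial CT, so only small
#' perturbations are plausible): rotation within +/-10 degrees, shifts
#' within +/-5% of the side, zoom in [0.9, 1.1], shear within +/-5
#' degrees, horizontal flipping enabled.
#'
#' @param rotationRange max absolute rotation, degrees
#' @param shiftRange max absolute x/y shift, fraction of the image side
#' @param zoomRange zoom interval; must contain 1
#' @param shearRange max absolute shear, degrees
#' @param horizontalFlip flip with probability 0.5 when TRUE
#' @param fillMode \code{"constant-zero"} pads exposed regions with 0;
#'   \code{"nearest-edge"} replicates edge pixels
#' @return a validated configuration (classed list)
#' @export
augmentationConfig <- function(rotationRange = 10, shiftRange = 0.05,
                               zoomRange = c(0.9, 1.1), shearRange = 5,
                               horizontalFlip = TRUE,
                               fillMode = c("constant-zero",
                                            "nearest-edge")) {
  fillMode <- match.arg(fillMode)
  stopifnot(rotationRange >= 0, shiftRange >= 0, shearRange >= 0,
            length(zoomRange) == 2L, diff(zoomRange) >= 0)
  if (zoomRange[1] > 1 || zoomRange[2] < 1)
    stop("zoomRange must contain 1")
  structure(list(rotationRange = rotationRange, shiftRange = shiftRange,
                 zoomRange = zoomRange, shearRange = shearRange,
                 horizontalFlip = horizontalFlip, fillMode = fillMode),
            class = "augmentationConfig")
}

#' Sample one set of affine transform parameters
#'
#' Each parameter is drawn uniformly from its configured range, from the R
#' session RNG (so a seeded training loop yields a reproducible
#' augmentation stream).
#'
#' @param config an \code{\link{augmentationConfig}}
#' @return list with \code{angle} and \code{shear} (degrees),
#'   \code{shiftX}, \code{shiftY} (fractions), \code{zoom}, \code{flip}
#'   (logical)
#' @export
sampleTransform <- function(config) {
  stopifnot(inherits(config, "augmentationConfig"))
  list(
    angle = runif(1, -config$rotationRange, config$rotationRange),
    shiftX = runif(1, -config$shiftRange, config$shiftRange),
    shiftY = runif(1, -config$shiftRange, config$shiftRange),
    zoom = runif(1, config$zoomRange[1], config$zoomRange[2]),
    shear = runif(1, -config$shearRange, config$shearRange),
    flip = config$horizontalFlip && runif(1) < 0.5
  )
}

identityTransform <- function() {
  list(angle = 0, shiftX = 0, shiftY = 0, zoom = 1, shear = 0, flip = FALSE)
}

# TRUE when every range is degenerate, so the augmentation stream could
# only ever produce the identity; the training loop then bypasses it
# (and its RNG draws) entirely.
isIdentityAugmentation <- function(config) {
  config$rotationRange == 0 && config$shiftRange == 0 &&
    config$shearRange == 0 && all(config$zoomRange == 1) &&
    !config$horizontalFlip
}

# 3x3 forward affine matrix about the image center for a parameter set.
# Coordinates follow the warping backend: the first coordinate is the row
# index and pixel i is centred at i - 1/2, so the geometric image center
# is (height/2, width/2).
affineMatrix <- function(params, height, width) {
  cx <- height / 2
  cy <- width / 2
  rad <- params$angle * pi / 180
  sh <- tan(params$shear * pi / 180)
  z <- params$zoom
  R <- matrix(c(cos(rad), sin(rad), 0, -sin(rad), cos(rad), 0, 0, 0, 1), 3)
  S <- diag(c(z, z, 1))
  Sh <- matrix(c(1, 0, 0, sh, 1, 0, 0, 0, 1), 3)
  Fl <- diag(c(1, if (params$flip) -1 else 1, 1))
  Tc <- matrix(c(1, 0, 0, 0, 1, 0, cx, cy, 1), 3)
  Tmc <- matrix(c(1, 0, 0, 0, 1, 0, -cx, -cy, 1), 3)
  Ts <- matrix(c(1, 0, 0, 0, 1, 0,
                 params$shiftX * height, params$shiftY * width, 1), 3)
  Ts %*% Tc %*% R %*% Sh %*% S %*% Fl %*% Tmc
}

padReplicate <- function(x, m) {
  h <- nrow(x); w <- ncol(x)
  ri <- c(rep(1L, m), seq_len(h), rep(h, m))
  ci <- c(rep(1L, m), seq_len(w), rep(w, m))
  x[ri, ci]
}

#' Apply one affine transform jointly to an image and mask
#'
#' The identical geometric map is applied to both grids: the image with
#' bilinear interpolation, the mask with nearest-neighbor so it stays
#' strictly binary. Output shape equals input shape. With identity
#' parameters the input is returned unchanged.
#'
#' @param image 2D intensity matrix
#' @param mask optional aligned binary matrix
#' @param params transform parameters from \code{\link{sampleTransform}}
#' @param fillMode \code{"constant-zero"} or \code{"nearest-edge"}
#' @return list with transformed \code{image} and \code{mask}
#' @export
applyTransform <- function(image, mask = NULL, params,
                           fillMode = "constant-zero") {
  if (!is.null(mask) && !identical(dim(mask), dim(image)))
    stop("image and mask must have the same shape")
  h <- nrow(image); w <- ncol(image)
  if (params$angle == 0 && params$shiftX == 0 && params$shiftY == 0 &&
      params$zoom == 1 && params$shear == 0 && !params$flip)
    return(list(image = image, mask = mask))
  pad <- 0L
  if (fillMode == "nearest-edge") {
    pad <- as.integer(ceiling(0.75 * max(h, w)))
    image <- padReplicate(image, pad)
    if (!is.null(mask)) mask <- padReplicate(mask, pad)
  }
  M <- affineMatrix(params, h, w)
  if (pad > 0L) {
    # conjugate by the padding translation so the transform acts about
    # the original image center with shift fractions of the original side
    Tp <- diag(3); Tp[1:2, 3] <- pad
    Tm <- diag(3); Tm[1:2, 3] <- -pad
    M <- Tp %*% M %*% Tm
  }
  m32 <- t(M[1:2, ])  # EBImage expects cbind(x, y, 1) %*% m
  outImg <- EBImage::imageData(EBImage::affine(image, m32,
                                               filter = "bilinear",
                                               bg.col = 0))
  outMask <- NULL
  if (!is.null(mask)) {
    outMask <- EBImage::imageData(EBImage::affine(mask, m32,
                                                  filter = "none",
                                                  bg.col = 0))
    outMask <- (outMask > 0.5) * 1
  }
  if (pad > 0L) {
    outImg <- outImg[pad + seq_len(h), pad + seq_len(w)]
    if (!is.null(outMask)) outMask <- outMask[pad + seq_len(h),
                                              pad + seq_len(w)]
  }
  list(image = outImg, mask = outMask)
}
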