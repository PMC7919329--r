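#' Configuration for the synthetic CT phantom generator
#'
#' Defines the statistical structure of generated axial slices: a bright
#' elliptical "liver" over a darker background, zero or more disk-shaped
#' lesions that are hypodense (negative contrast) or hyperdense (positive
#' contrast) relative to the liver, additive Gaussian noise, and class
#' imbalance comparable to abdominal CT liver/tumor masks. The defaults are
#' calibrated so that pooled foreground:background pixel ratios over many
#' slices are close to 1:9 for liver masks and 1:85 for tumor masks (over
#' lesion-carrying slices), the imbalance regime this method targets.
#'
#' All geometric parameters are fractions of the image side, so the same
#' configuration scales to any resolution. Lesions are always placed
#' entirely inside the liver.
#'
#' @param imageSize pixels per side (square slices), default 128
#' @param liverAxesRange ellipse semi-axis range as fractions of the side
#' @param liverIntensity,backgroundIntensity mean intensities in [0, 1]
#' @param tumorCountRange integer interval of lesions per lesion-carrying
#'   slice
#' @param tumorRadiusRange lesion radius range as fractions of the side
#' @param tumorContrast signed intensity offset added inside lesions;
#'   negative = hypodense, positive = hyperdense
#' @param noiseSd standard deviation of additive Gaussian noise (intensity
#'   units; values are clamped to [0, 1] afterwards)
#' @param tumorProbability chance that a slice carries at least one lesion
#' @param boundaryAmp amplitude of the low-frequency perturbation of the
#'   liver boundary (0 gives an exact ellipse)
#' @param centerJitter liver center jitter as a fraction of the side
#' @param seed optional integer seed used by \code{\link{generateVolume}}
#' @return a validated configuration (classed list)
#' @seealso \code{\link{generateSlice}}, \code{\link{generateVolume}}
#' @export
phantomConfig <- function(imageSize = 128L,
                          liverAxesRange = c(0.14, 0.215),
                          liverIntensity = 0.6,
                          backgroundIntensity = 0.2,
                          tumorCountRange = c(1L, 2L),
                          tumorRadiusRange = c(0.03, 0.068),
                          tumorContrast = -0.3,
                          noiseSd = 0.05,
                          tumorProbability = 0.6,
                          boundaryAmp = 0.05,
                          centerJitter = 0.05,
                          seed = NULL) {
  stopifnot(
    length(imageSize) == 1L, imageSize >= 8,
    length(liverAxesRange) == 2L, all(liverAxesRange > 0),
    diff(liverAxesRange) >= 0,
    liverIntensity >= 0, liverIntensity <= 1,
    backgroundIntensity >= 0, backgroundIntensity <= 1,
    length(tumorCountRange) == 2L, all(tumorCountRange >= 0),
    diff(tumorCountRange) >= 0,
    length(tumorRadiusRange) == 2L, all(tumorRadiusRange > 0),
    diff(tumorRadiusRange) >= 0,
    tumorContrast >= -1, tumorContrast <= 1,
    noiseSd >= 0,
    tumorProbability >= 0, tumorProbability <= 1,
    boundaryAmp >= 0, centerJitter >= 0
  )
  tumorMean <- liverIntensity + tumorContrast
  if (tumorMean < 0 || tumorMean > 1)
    stop("liverIntensity + tumorContrast must stay in [0, 1], got ",
         tumorMean)
  cfg <- list(
    imageSize = as.integer(imageSize),
    liverAxesRange = liverAxesRange,
    liverIntensity = liverIntensity,
    backgroundIntensity = backgroundIntensity,
    tumorCountRange = as.integer(tumorCountRange),
    tumorRadiusRange = tumorRadiusRange,
    tumorContrast = tumorContrast,
    noiseSd = noiseSd,
    tumorProbability = tumorProbability,
    boundaryAmp = boundaryAmp,
    centerJitter = centerJitter,
    seed = seed
  )
  class(cfg) <- "phantomConfig"
  cfg
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Generate one synthetic axial slice with ground-truth masks
#'
#' Draws a randomly placed, rotated and (optionally) boundary-perturbed
#' liver ellipse, places lesion disks fully inside it, shades lesions by
#' \code{tumorContrast}, adds Gaussian noise and clamps intensities to
#' [0, 1]. Randomness comes from the R session RNG, so a \code{set.seed()}
#' call before a sequence of draws makes the sequence reproducible.
#'
#' @param config a \code{\link{phantomConfig}}
#' @param maxTries placement attempts per lesion before failing with a
#'   descriptive error (lesions must lie entirely inside the liver)
#' @return list with elements \code{image} (H x W in [0, 1]),
#'   \code{liverMask} and \code{tumorMask} (binary H x W matrices)
#' @examples
#' set.seed(1)
#' sl <- generateSlice(phantomConfig(imageSize = 64))
#' range(sl$image)
#' sum(sl$tumorMask * (1 - sl$liverMask)) # lesions nest inside the liver
#' @export
generateSlice <- function(config, maxTries = 50L) {
  stopifnot(inherits(config, "phantomConfig"))
  S <- config$imageSize
  X <- matrix(seq_len(S), S, S)           # row coordinate
  Y <- t(X)                               # column coordinate
  cx <- S / 2 + runif(1, -1, 1) * config$centerJitter * S
  cy <- S / 2 + runif(1, -1, 1) * config$centerJitter * S
  phi <- runif(1, 0, pi)
  a <- runif(1, config$liverAxesRange[1], config$liverAxesRange[2]) * S
  b <- runif(1, config$liverAxesRange[1], config$liverAxesRange[2]) * S
  dx <- X - cx; dy <- Y - cy
  xr <- dx * cos(phi) + dy * sin(phi)
  yr <- -dx * sin(phi) + dy * cos(phi)
  rn2 <- (xr / a)^2 + (yr / b)^2
  if (config$boundaryAmp > 0) {
    amp <- runif(2, 0, config$boundaryAmp)
    pha <- runif(2, 0, 2 * pi)
    theta <- atan2(yr, xr)
    scale <- 1 + amp[1] * cos(2 * theta + pha[1]) +
      amp[2] * cos(3 * theta + pha[2])
  } else {
    scale <- 1
  }
  liver <- (rn2 <= scale^2) * 1

  tumor <- matrix(0, S, S)
  maxCount <- config$tumorCountRange[2]
  nLesions <- 0L
  if (maxCount > 0 && runif(1) < config$tumorProbability)
    nLesions <- sample(seq(max(1L, config$tumorCountRange[1]), maxCount), 1L)
  if (nLesions > 0L) {
    inside <- which(liver == 1)
    for (i in seq_len(nLesions)) {
      r <- runif(1, config$tumorRadiusRange[1], config$tumorRadiusRange[2]) * S
      placed <- FALSE
      for (try in seq_len(maxTries)) {
        ctr <- inside[sample.int(length(inside), 1L)]
        ch <- (ctr - 1L) %% S + 1L
        cw <- (ctr - 1L) %/% S + 1L
        disk <- (X - ch)^2 + (Y - cw)^2 <= r^2
        if (all(liver[disk] == 1)) {
          tumor[disk] <- 1
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop(sprintf(paste0(
          "could not place a tumor lesion of radius %.1f px inside the ",
          "liver (semi-axes %.1f x %.1f px) after %d attempts; the tumor ",
          "radius range likely exceeds the liver axes"),
          r, a, b, maxTries))
    }
  }

  img <- config$backgroundIntensity +
    (config$liverIntensity - config$backgroundIntensity) * liver +
    config$tumorContrast * tumor
  if (config$noiseSd > 0)
    img <- img + rnorm(S * S, sd = config$noiseSd)
  list(image = clamp01(matrix(img, S, S)), liverMask = liver,
       tumorMask = tumor)
}

#' Generate a synthetic volume with empty end slices
#'
#' Stacks \code{nSlices} phantom slices into a \linkS4class{VolumePair}.
#' The first and last \code{ceiling(emptyMargin * nSlices)} slices contain
#' background and noise only (no liver), emulating the start/end of an
#' abdominal scan where the liver is absent -- exactly the slices the
#' class-balancing filter is meant to remove.
#'
#' @param config a \code{\link{phantomConfig}}
#' @param nSlices number of slices (>= 1)
#' @param emptyMargin fraction in [0, 0.4] of empty slices at each end
#' @param sliceSpacing slice spacing in mm (metadata only)
#' @param seed integer seed; defaults to \code{config$seed}. \code{NULL}
#'   continues the session RNG stream.
#' @return a \linkS4class{VolumePair}
#' @export
generateVolume <- function(config, nSlices, emptyMargin = 0,
                           sliceSpacing = 1, seed = config$seed) {
  stopifnot(inherits(config, "phantomConfig"))
  if (length(nSlices) != 1L || nSlices < 1)
    stop("nSlices must be a positive integer")
  if (emptyMargin < 0 || emptyMargin > 0.4)
    stop("emptyMargin must be in [0, 0.4]")
  nSlices <- as.integer(nSlices)
  if (!is.null(seed)) set.seed(seed)
  m <- as.integer(ceiling(emptyMargin * nSlices))
  if (2L * m >= nSlices && emptyMargin > 0)
    stop("emptyMargin leaves no non-empty slices for nSlices = ", nSlices)
  S <- config$imageSize
  imgs <- array(0, c(S, S, nSlices))
  lv <- array(0, c(S, S, nSlices))
  tm <- array(0, c(S, S, nSlices))
  emptyIdx <- c(seq_len(m), nSlices - seq_len(m) + 1L)
  for (i in seq_len(nSlices)) {
    if (i %in% emptyIdx) {
      bg <- config$backgroundIntensity
      if (config$noiseSd > 0) bg <- bg + rnorm(S * S, sd = config$noiseSd)
      imgs[, , i] <- clamp01(matrix(bg, S, S))
    } else {
      sl <- generateSlice(config)
      imgs[, , i] <- sl$image
      lv[, , i] <- sl$liverMask
      tm[, , i] <- sl$tumorMask
    }
  }
  VolumePair(imgs, lv, tm, sliceSpacing)
}
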