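#' Pixel-wise union of binary masks
#'
#' Merges several binary masks of the same shape into one (logical OR).
#' Used to collapse per-lesion mask files into a single tumor mask before
#' training.
#'
#' @param masks list of binary matrices/arrays of identical shape
#' @return binary mask of the same shape
#' @examples
#' a <- matrix(0, 2, 2); a[1, 1] <- 1
#' b <- matrix(0, 2, 2); b[2, 2] <- 1
#' mergeMasks(list(a, b))
#' @export
mergeMasks <- function(masks) {
  if (!is.list(masks) || length(masks) == 0L)
    stop("masks must be a non-empty list of binary grids")
  d <- dim(masks[[1L]])
  for (i in seq_along(masks)) {
    if (!identical(dim(masks[[i]]), d))
      stop("mask ", i, " has a different shape than mask 1")
    if (!all(masks[[i]] %in% c(0, 1)))
      stop("mask ", i, " is not binary")
  }
  out <- Reduce(pmax, masks)
  out
}

#' Split a combined {0,1,2} label volume into liver and tumor masks
#'
#' Combined segmentation volumes label background 0, liver 1 and tumor 2,
#' with tumor voxels lying anatomically inside the liver. The liver mask is
#' therefore \code{label >= 1} (tumor voxels are liver tissue) and the
#' tumor mask is \code{label == 2}.
#'
#' @param labels integer matrix or array with values in {0, 1, 2}
#' @return list with binary \code{liver} and \code{tumor} components of the
#'   same shape as \code{labels}
#' @seealso \code{\link{combineLabels}} for the inverse
#' @export
splitCombinedLabels <- function(labels) {
  bad <- setdiff(unique(as.vector(labels)), c(0, 1, 2))
  if (length(bad) > 0L)
    stop("label volume contains out-of-range value(s): ",
         paste(bad, collapse = ", "), " (allowed: 0, 1, 2)")
  liver <- (labels >= 1) * 1
  tumor <- (labels == 2) * 1
  dim(liver) <- dim(labels)
  dim(tumor) <- dim(labels)
  list(liver = liver, tumor = tumor)
}

#' Combine liver and tumor masks into a {0,1,2} label volume
#'
#' Inverse of \code{\link{splitCombinedLabels}}: tumor (2) overrides liver
#' (1). Requires the tumor mask to be nested inside the liver mask.
#'
#' @param liver,tumor binary masks of identical shape
#' @return integer label array with values in {0, 1, 2}
#' @export
combineLabels <- function(liver, tumor) {
  stopifnot(identical(dim(liver), dim(tumor)),
            all(liver %in% c(0, 1)), all(tumor %in% c(0, 1)))
  if (any(tumor > liver))
    stop("tumor mask must be nested inside the liver mask")
  out <- liver + tumor
  dim(out) <- dim(liver)
  out
}

#' Foreground to background pixel ratio
#'
#' The class-imbalance statistic: number of white (foreground) pixels
#' divided by number of black (background) pixels, computed over a single
#' mask or pooled over a mask stack. A 1:9 imbalance yields 0.111...
#'
#' @param mask binary matrix or array
#' @return non-negative ratio
#' @export
pixelRatio <- function(mask) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  fg <- sum(mask)
  bg <- length(mask) - fg
  if (bg == 0)
    stop("mask has no background pixels; the white:black ratio is undefined")
  fg / bg
}

#' Class-balancing slice filter
#'
#' Removes slices whose target mask carries no foreground at all -- the
#' "no liver information" / "no tumor information" slices -- and reports
#' the pooled white:black pixel ratio before and after removal. Removing
#' empty slices can only concentrate foreground, so the ratio never
#' decreases.
#'
#' @param volume a \linkS4class{VolumePair}
#' @param target \code{"liver"} or \code{"tumor"}: which mask must be
#'   non-empty for a slice to be kept
#' @return list with \code{kept} (indices of retained slices) and
#'   \code{report}, a \code{ClassBalanceReport} with fields
#'   \code{nTotal}, \code{nKept}, \code{nRemoved}, \code{ratioBefore},
#'   \code{ratioAfter}
#' @examples
#' set.seed(7)
#' vol <- generateVolume(phantomConfig(imageSize = 32), 10, emptyMargin = 0.2)
#' filterSlices(vol, "liver")$report
#' @export
filterSlices <- function(volume, target = c("liver", "tumor")) {
  stopifnot(is(volume, "VolumePair"))
  target <- match.arg(target)
  masks <- if (target == "liver") volume@liverMasks else volume@tumorMasks
  perSlice <- colSums(masks, dims = 2L)
  kept <- which(perSlice > 0)
  ratioBefore <- pixelRatio(masks)
  ratioAfter <- if (length(kept) > 0L)
    pixelRatio(masks[, , kept, drop = FALSE]) else 0
  report <- structure(
    list(target = target,
         nTotal = length(perSlice),
         nKept = length(kept),
         nRemoved = length(perSlice) - length(kept),
         ratioBefore = ratioBefore,
         ratioAfter = ratioAfter),
    class = "ClassBalanceReport")
  list(kept = kept, report = report)
}

#' @export
print.ClassBalanceReport <- function(x, ...) {
  cat(sprintf("Class balance report (target: %s)\n", x$target))
  cat(sprintf("  slices: %d total, %d kept, %d removed\n",
              x$nTotal, x$nKept, x$nRemoved))
  cat(sprintf("  white:black ratio %.4f -> %.4f\n",
              x$ratioBefore, x$ratioAfter))
  invisible(x)
}

#' Resize and normalize one slice with its mask
#'
#' Images are resized with bilinear interpolation and then min-max
#' normalized to [0, 1]; masks are resized with nearest-neighbor so they
#' stay strictly binary. Output dimensions are
#' \code{floor(original * scale)}.
#'
#' @param image 2D intensity matrix
#' @param mask optional aligned binary matrix
#' @param scale resize factor in (0, 1]; the reference pipeline uses 0.25
#'   (512 to 128 pixels)
#' @return list with resized \code{image} (normalized to [0, 1]) and
#'   \code{mask} (binary, or NULL if none supplied)
#' @export
preprocessSlice <- function(image, mask = NULL, scale = 0.25) {
  stopifnot(is.matrix(image), scale > 0, scale <= 1)
  if (!is.null(mask) && !identical(dim(mask), dim(image)))
    stop("image and mask must have the same shape")
  h <- floor(nrow(image) * scale)
  w <- floor(ncol(image) * scale)
  img <- if (scale == 1) image else
    EBImage::imageData(EBImage::resize(image, w = h, h = w,
                                       filter = "bilinear"))
  rng <- range(img)
  if (rng[2] - rng[1] <= 0) {
    warning("constant image: min-max normalization returns all zeros")
    img <- array(0, dim(img))
  } else {
    img <- (img - rng[1]) / (rng[2] - rng[1])
  }
  msk <- NULL
  if (!is.null(mask)) {
    msk <- if (scale == 1) mask else
      EBImage::imageData(EBImage::resize(mask, w = h, h = w,
                                         filter = "none"))
    msk <- (msk > 0.5) * 1
  }
  list(image = img, mask = msk)
}

#' Preprocess every slice of a stack
#'
#' Vectorized convenience wrapper around \code{\link{preprocessSlice}}.
#'
#' @param images array (H, W, n)
#' @param masks optional aligned binary array
#' @param scale resize factor in (0, 1]
#' @return list of resized/normalized \code{images} and \code{masks} arrays
#' @export
preprocessStack <- function(images, masks = NULL, scale = 0.25) {
  n <- dim(images)[3L]
  first <- preprocessSlice(images[, , 1L],
                           if (!is.null(masks)) masks[, , 1L], scale)
  d <- dim(first$image)
  outI <- array(0, c(d, n))
  outM <- if (!is.null(masks)) array(0, c(d, n)) else NULL
  outI[, , 1L] <- first$image
  if (!is.null(masks)) outM[, , 1L] <- first$mask
  for (i in seq_len(n)[-1L]) {
    p <- preprocessSlice(images[, , i],
                         if (!is.null(masks)) masks[, , i], scale)
    outI[, , i] <- p$image
    if (!is.null(masks)) outM[, , i] <- p$mask
  }
  list(images = outI, masks = outM)
}
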