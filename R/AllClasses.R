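#' Paired image and mask stacks for one scan volume
#'
#' A \code{VolumePair} holds an ordered stack of axial 2D intensity slices
#' together with the aligned binary liver and tumor mask stacks, plus the
#' slice spacing in millimetres (informational). It is the unit of dataset
#' ingestion: phantom volumes, PNG slice directories and NIfTI volumes are
#' all read into this container.
#'
#' Validity requires identical dimensions for the three stacks, strictly
#' binary masks, and anatomical nesting: every tumor foreground pixel must
#' also be liver foreground.
#'
#' @slot images numeric array (H, W, n) of intensities in [0, 1]
#' @slot liverMasks numeric array (H, W, n) with values in {0, 1}
#' @slot tumorMasks numeric array (H, W, n) with values in {0, 1}
#' @slot sliceSpacing single numeric, slice spacing in mm
#'
#' @aliases VolumePair-class
#' @export
setClass("VolumePair",
  representation(
    images = "array",
    liverMasks = "array",
    tumorMasks = "array",
    sliceSpacing = "numeric"
  )
)

setValidity("VolumePair", function(object) {
  di <- dim(object@images)
  if (length(di) != 3L) return("images must be a 3D array (H, W, n)")
  if (!identical(di, dim(object@liverMasks)) ||
      !identical(di, dim(object@tumorMasks)))
    return("images, liverMasks and tumorMasks must have identical dimensions")
  if (!all(object@liverMasks %in% c(0, 1)))
    return("liverMasks must contain only values {0, 1}")
  if (!all(object@tumorMasks %in% c(0, 1)))
    return("tumorMasks must contain only values {0, 1}")
  if (any(object@tumorMasks > object@liverMasks))
    return("every tumor foreground pixel must also be liver foreground")
  if (length(object@sliceSpacing) != 1L || object@sliceSpacing <= 0)
    return("sliceSpacing must be a single positive number")
  TRUE
})

#' Construct a VolumePair
#'
#' @param images numeric array (H, W, n) of slice intensities
#' @param liverMasks,tumorMasks aligned binary arrays (H, W, n)
#' @param sliceSpacing slice spacing in mm (informational; default 1)
#' @return a validated \linkS4class{VolumePair}
#' @examples
#' img <- array(runif(4 * 4 * 2), c(4, 4, 2))
#' lv <- array(0, c(4, 4, 2)); lv[2:3, 2:3, ] <- 1
#' vp <- VolumePair(img, lv, array(0, c(4, 4, 2)))
#' nSlices(vp)
#' @export
VolumePair <- function(images, liverMasks, tumorMasks, sliceSpacing = 1) {
  new("VolumePair", images = images, liverMasks = liverMasks,
      tumorMasks = tumorMasks, sliceSpacing = sliceSpacing)
}

#' @rdname VolumePair
#' @param x a \code{VolumePair}
#' @export
setGeneric("imageStack", function(x) standardGeneric("imageStack"))

#' @rdname VolumePair
#' @export
setMethod("imageStack", "VolumePair", function(x) x@images)

#' @rdname VolumePair
#' @export
setGeneric("liverMasks", function(x) standardGeneric("liverMasks"))

#' @rdname VolumePair
#' @export
setMethod("liverMasks", "VolumePair", function(x) x@liverMasks)

#' @rdname VolumePair
#' @export
setGeneric("tumorMasks", function(x) standardGeneric("tumorMasks"))

#' @rdname VolumePair
#' @export
setMethod("tumorMasks", "VolumePair", function(x) x@tumorMasks)

#' @rdname VolumePair
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' @rdname VolumePair
#' @export
setMethod("nSlices", "VolumePair", function(x) dim(x@images)[3L])

setMethod("show", "VolumePair", function(object) {
  d <- dim(object@images)
  cat(sprintf("VolumePair: %d slices of %d x %d (spacing %.2f mm)\n",
              d[3], d[1], d[2], object@sliceSpacing))
  cat(sprintf("  liver foreground: %d px | tumor foreground: %d px\n",
              sum(object@liverMasks), sum(object@tumorMasks)))
})

#' U-Net segmentation model
#'
#' Container for a constructed U-Net: the architecture configuration and a
#' mutable state environment holding the trainable parameters and the
#' batch-normalization running statistics. State lives in an environment so
#' that training updates in place; use \code{\link{modelParameters}} to
#' obtain a snapshot copy.
#'
#' @slot config list, the architecture configuration
#'   (see \code{\link{architectureConfig}})
#' @slot state environment with elements \code{params} (named list of
#'   weight arrays) and \code{running} (per batch-norm layer running mean
#'   and variance)
#'
#' @aliases UNetModel-class
#' @export
setClass("UNetModel",
  representation(config = "list", state = "environment")
)

setMethod("show", "UNetModel", function(object) {
  cfg <- object@config
  filt <- cfg$baseFilters * 2^(seq_len(cfg$depth) - 1L)
  cat("UNetModel (encoder-decoder with skip connections)\n")
  cat(sprintf("  depth %d | filters %s | bottleneck %d | dropout %.2f\n",
              cfg$depth, paste(filt, collapse = "-"),
              bottleneckFilters(cfg), cfg$dropoutRate))
  cat(sprintf("  input %d x %d x %d -> output %d channel(s), sigmoid\n",
              cfg$inputSize, cfg$inputSize, cfg$inChannels, cfg$outChannels))
  cat(sprintf("  trainable parameters: %s\n",
              format(countParameters(object), big.mark = ",")))
})
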