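#' Confusion counts between a predicted and a ground-truth mask
#'
#' Exact per-pixel tallies: TP (foreground predicted foreground), TN
#' (background predicted background), FN (missed foreground), FP
#' (background predicted foreground). The four counts always sum to the
#' pixel count of the grids.
#'
#' @param pred,truth binary grids of identical shape
#' @return a \code{ConfusionCounts} object
#' @export
confusionCounts <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth)) || length(pred) != length(truth))
    stop("pred and truth must have the same shape")
  if (!all(pred %in% c(0, 1)) || !all(truth %in% c(0, 1)))
    stop("masks must be binary")
  tp <- sum(pred * truth)
  fp <- sum(pred * (1 - truth))
  fn <- sum((1 - pred) * truth)
  tn <- length(pred) - tp - fp - fn
  new("ConfusionCounts", TP = tp, TN = tn, FP = fp, FN = fn)
}

#' @rdname confusionCounts
#' @aliases ConfusionCounts-class
#' @slot TP,TN,FP,FN non-negative pixel counts
#' @export
setClass("ConfusionCounts",
  representation(TP = "numeric", TN = "numeric", FP = "numeric",
                 FN = "numeric"),
  validity = function(object) {
    v <- c(object@TP, object@TN, object@FP, object@FN)
    if (any(v < 0)) return("counts must be non-negative")
    TRUE
  })

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts: TP=%g TN=%g FP=%g FN=%g\n",
              object@TP, object@TN, object@FP, object@FN))
})

#' Dice similarity coefficient
#'
#' Overlap between two binary masks, \code{2TP / (2TP + FP + FN)}, from 0
#' (no overlap) to 1 (perfect). When both masks are empty
#' (\code{2TP + FP + FN = 0}) the result is defined as 1: predicting
#' "no foreground" on a foreground-free slice is a perfect answer.
#'
#' @param counts a \code{ConfusionCounts} object
#' @return fraction in [0, 1]
#' @export
dsc <- function(counts) {
  d <- 2 * counts@TP + counts@FP + counts@FN
  if (d == 0) return(1)
  2 * counts@TP / d
}

#' Jaccard similarity coefficient (intersection over union)
#'
#' \code{TP / (TP + FP + FN)}; 1 when both masks are empty (same
#' convention as \code{\link{dsc}}). Algebraically
#' \code{jsc = dsc / (2 - dsc)}.
#'
#' @param counts a \code{ConfusionCounts} object
#' @return fraction in [0, 1]
#' @export
jsc <- function(counts) {
  d <- counts@TP + counts@FP + counts@FN
  if (d == 0) return(1)
  counts@TP / d
}

#' Pixel accuracy
#'
#' Fraction of pixels classified correctly,
#' \code{(TP + TN) / (TP + TN + FP + FN)}.
#'
#' @param counts a \code{ConfusionCounts} object
#' @return fraction in [0, 1]
#' @export
pixelAccuracy <- function(counts) {
  tot <- counts@TP + counts@TN + counts@FP + counts@FN
  if (tot == 0) stop("empty grids: accuracy undefined")
  (counts@TP + counts@TN) / tot
}

#' Symmetric volume difference
#'
#' \code{SVD = 1 - DSC}; 0 for a perfect segmentation.
#'
#' @param dscValue Dice coefficient in [0, 1]
#' @return fraction in [0, 1]
#' @export
svdScore <- function(dscValue) {
  if (any(dscValue < 0) || any(dscValue > 1))
    stop("dscValue must lie in [0, 1]")
  1 - dscValue
}

#' Evaluate a stack of predicted masks against ground truth
#'
#' Computes DSC, JSC, pixel accuracy and SVD per slice and aggregated. Two
#' aggregations are reported: the per-slice mean (the headline number for
#' an average dice score over a test set) and the pooled version computed
#' from summed confusion counts; they differ whenever slice difficulty
#' varies. Per-slice standard deviation and standard error of the DSC are
#' both included.
#'
#' @param pred,truth binary arrays (H, W, n) or matrices
#' @param aggregation \code{"per-slice-mean"} (headline) or \code{"pooled"}
#' @return a \code{MetricsReport}: list with \code{dsc}, \code{jsc},
#'   \code{accuracy}, \code{svd}, \code{nSlices}, \code{aggregation},
#'   \code{dscSd}, \code{dscSe} and a \code{perSlice} data.frame
#' @export
evaluateMasks <- function(pred, truth,
                          aggregation = c("per-slice-mean", "pooled")) {
  aggregation <- match.arg(aggregation)
  if (is.matrix(pred)) pred <- array(pred, c(dim(pred), 1L))
  if (is.matrix(truth)) truth <- array(truth, c(dim(truth), 1L))
  if (!identical(dim(pred), dim(truth)))
    stop("pred and truth must have the same shape")
  n <- dim(pred)[3L]
  per <- data.frame(slice = seq_len(n), dsc = NA_real_, jsc = NA_real_,
                    accuracy = NA_real_, svd = NA_real_)
  pooled <- new("ConfusionCounts", TP = 0, TN = 0, FP = 0, FN = 0)
  for (i in seq_len(n)) {
    cc <- confusionCounts(pred[, , i], truth[, , i])
    per$dsc[i] <- dsc(cc)
    per$jsc[i] <- jsc(cc)
    per$accuracy[i] <- pixelAccuracy(cc)
    per$svd[i] <- svdScore(per$dsc[i])
    pooled@TP <- pooled@TP + cc@TP; pooled@TN <- pooled@TN + cc@TN
    pooled@FP <- pooled@FP + cc@FP; pooled@FN <- pooled@FN + cc@FN
  }
  if (aggregation == "per-slice-mean") {
    d <- mean(per$dsc); j <- mean(per$jsc); a <- mean(per$accuracy)
  } else {
    d <- dsc(pooled); j <- jsc(pooled); a <- pixelAccuracy(pooled)
  }
  structure(list(dsc = d, jsc = j, accuracy = a, svd = svdScore(d),
                 nSlices = n, aggregation = aggregation,
                 dscSd = stats::sd(per$dsc),
                 dscSe = stats::sd(per$dsc) / sqrt(n),
                 perSlice = per, pooledCounts = pooled),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf("MetricsReport (%s over %d slice%s)\n", x$aggregation,
              x$nSlices, if (x$nSlices == 1) "" else "s"))
  cat(sprintf("  DSC %.4f | JSC %.4f | accuracy %.4f | SVD %.4f\n",
              x$dsc, x$jsc, x$accuracy, x$svd))
  if (x$nSlices > 1)
    cat(sprintf("  DSC sd %.4f, se %.4f\n", x$dscSd, x$dscSe))
  invisible(x)
}

#' Render an error-overlay image
#'
#' Composites segmentation agreement over the grayscale background: missed
#' foreground (FN) in cyan, false foreground (FP) in magenta, correctly
#' segmented foreground (TP) in yellow.
#'
#' @param pred,truth binary masks
#' @param background grayscale image in [0, 1], same shape
#' @return RGB array (H, W, 3)
#' @export
overlapImage <- function(pred, truth, background) {
  stopifnot(identical(dim(pred), dim(truth)),
            identical(dim(pred), dim(background)))
  out <- array(rep(clamp01(background), 3), c(dim(pred), 3))
  fn <- pred == 0 & truth == 1
  fp <- pred == 1 & truth == 0
  tp <- pred == 1 & truth == 1
  r <- out[, , 1]; g <- out[, , 2]; b <- out[, , 3]
  r[fn] <- 0; g[fn] <- 1; b[fn] <- 1    # cyan
  r[fp] <- 1; g[fp] <- 0; b[fp] <- 1    # magenta
  r[tp] <- 1; g[tp] <- 1; b[tp] <- 0    # yellow
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  out
}
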