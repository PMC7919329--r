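#' Weighted dice loss
#'
#' Negative weighted Dice overlap, \code{-W * (2TP) / (2TP + FP + FN)},
#' with a smoothing constant \code{epsilon} added to numerator and
#' denominator so the empty-prediction / empty-target case evaluates to
#' \code{-W} (a correct "nothing to segment" answer). \code{W} rescales
#' the loss to counteract foreground/background class imbalance; the loss
#' is linear in \code{W} and lies in \code{[-W, 0)}.
#'
#' In soft mode the counts are probabilistic
#' (\code{TP = sum(p * y)}, \code{FP = sum(p * (1 - y))},
#' \code{FN = sum((1 - p) * y)}), making the loss differentiable -- the
#' form used for training. In hard mode the prediction is thresholded
#' first; then \code{-loss / W} equals the Dice coefficient of the
#' thresholded mask (up to smoothing).
#'
#' @param pred numeric grid of probabilities in [0, 1]
#' @param target binary grid of the same shape
#' @param W positive weight factor (default 1)
#' @param epsilon positive smoothing constant (default 1)
#' @param soft probabilistic counts (TRUE) or thresholded counts
#' @param threshold threshold for hard mode
#' @return a single number in \code{[-W, 0)}
#' @examples
#' y <- matrix(c(1, 0, 1, 0), 2)
#' weightedDiceLoss(y, y)            # perfect prediction: ~ -1
#' weightedDiceLoss(y, y, W = 2)     # scales linearly in W
#' @export
weightedDiceLoss <- function(pred, target, W = 1, epsilon = 1,
                             soft = TRUE, threshold = 0.5) {
  checkLossInputs(pred, target, W, epsilon)
  if (!soft) pred <- (pred >= threshold) * 1
  tp <- sum(pred * target)
  denom <- sum(pred) + sum(target)  # = 2TP + FP + FN
  -W * (2 * tp + epsilon) / (denom + epsilon)
}

#' Gradient of the soft weighted dice loss
#'
#' Analytic derivative of \code{\link{weightedDiceLoss}} (soft mode) with
#' respect to each predicted probability.
#'
#' @inheritParams weightedDiceLoss
#' @return grid of the same shape as \code{pred}
#' @export
weightedDiceLossGrad <- function(pred, target, W = 1, epsilon = 1) {
  checkLossInputs(pred, target, W, epsilon)
  A <- 2 * sum(pred * target) + epsilon
  B <- sum(pred) + sum(target) + epsilon
  g <- -W * (2 * target * B - A) / B^2
  dim(g) <- dim(pred)
  g
}

checkLossInputs <- function(pred, target, W, epsilon) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target must have the same shape")
  if (W <= 0) stop("W must be positive")
  if (epsilon <= 0) stop("epsilon must be positive")
  invisible(TRUE)
}

#' Binary cross-entropy
#'
#' Mean negative log-likelihood of the binary targets under the predicted
#' per-pixel probabilities:
#' \code{-(1/N) * sum(y * log(p) + (1 - y) * log(1 - p))}. Each logarithm
#' argument is clipped from below at \code{clip}, which bounds the loss on
#' confident mistakes while leaving a perfect prediction at exactly 0.
#'
#' @param pred numeric grid of probabilities in [0, 1]
#' @param target binary grid of the same shape
#' @param clip clipping constant protecting the logarithms
#' @return non-negative number; 0 iff the prediction equals the binary
#'   target
#' @export
binaryCrossEntropy <- function(pred, target, clip = 1e-7) {
  if (!identical(dim(pred), dim(target)) ||
      length(pred) != length(target))
    stop("pred and target must have the same shape")
  -mean(target * log(pmax(pred, clip)) +
          (1 - target) * log(pmax(1 - pred, clip)))
}

#' Estimate the dice loss weight factor from a mask dataset
#'
#' In \code{"inverse-ratio"} mode returns the pooled background:foreground
#' pixel ratio of the target masks (the reciprocal of
#' \code{\link{pixelRatio}}), so rarer foreground earns a larger weight.
#' In \code{"fixed"} mode returns the supplied constant unchanged.
#'
#' @param masks binary array or list of binary masks (the training
#'   targets)
#' @param mode \code{"fixed"} or \code{"inverse-ratio"}
#' @param W constant returned in fixed mode
#' @return positive weight
#' @export
estimateWeight <- function(masks, mode = c("fixed", "inverse-ratio"),
                           W = 1) {
  mode <- match.arg(mode)
  if (mode == "fixed") {
    if (W <= 0) stop("fixed weight W must be positive")
    return(W)
  }
  if (is.list(masks)) masks <- simplify2array(masks)
  fg <- sum(masks)
  bg <- length(masks) - fg
  if (fg == 0)
    stop("pooled dataset has no foreground pixels; filter out empty ",
         "slices (filterSlices) before estimating the weight")
  if (bg == 0)
    stop("pooled dataset has no background pixels; the inverse ratio is ",
         "undefined")
  bg / fg
}
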