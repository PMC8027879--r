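# Segmentation objective: weighted binary cross-entropy plus soft Dice.
#
# The cross-entropy is the standard negative log-likelihood with an optional
# per-pixel weight map; the Dice term uses the squared-denominator soft form
# 1 - (2*sum(p*g) + s) / (sum(g^2) + sum(p^2) + s) with smoothing s = 1 so
# the empty-vs-empty case is defined (loss 0). Both terms are averaged over
# pixels so magnitudes are resolution-independent; averaging is a monotone
# rescale of the summed form and does not move the optimum.

.ce_eps <- 1e-7

#' Weighted pixel-wise binary cross-entropy loss
#'
#' `CE = -mean( w * (g * log p + (1 - g) * log(1 - p)) )` with predictions
#' clipped to `[eps, 1 - eps]`. The weight map defaults to all ones.
#'
#' @param pred Probability map, values in \[0, 1\].
#' @param gt Binary ground-truth mask (0/1).
#' @param w Optional non-negative per-pixel weight map.
#' @return Non-negative scalar.
#' @export
ce_loss <- function(pred, gt, w = NULL) {
  stop_if_shape_mismatch(pred, gt, "pred and gt")
  if (!all(is.finite(pred))) stop("non-finite predictions", call. = FALSE)
  if (is.null(w)) w <- 1 else {
    stop_if_shape_mismatch(pred, w, "pred and weight map")
    if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  }
  p <- clip(pred, .ce_eps, 1 - .ce_eps)
  -mean(w * (gt * log(p) + (1 - gt) * log(1 - p)))
}

#' Soft Dice loss (squared denominator)
#'
#' `1 - (2*sum(p*g) + s) / (sum(g^2) + sum(p^2) + s)` with smoothing
#' `s = 1`. Equals 0 for a perfect binary prediction and approaches 1 for
#' disjoint non-empty prediction and truth.
#'
#' @inheritParams ce_loss
#' @param smooth Smoothing constant added to numerator and denominator.
#' @return Scalar in \[0, 1\].
#' @export
dice_loss <- function(pred, gt, smooth = 1) {
  stop_if_shape_mismatch(pred, gt, "pred and gt")
  1 - (2 * sum(pred * gt) + smooth) /
    (sum(gt^2) + sum(pred^2) + smooth)
}

#' Combined training objective: cross-entropy plus Dice
#'
#' @inheritParams ce_loss
#' @return `ce_loss(pred, gt, w) + dice_loss(pred, gt)`, with no extra
#'   weighting between the two terms.
#' @export
total_loss <- function(pred, gt, w = NULL) {
  ce_loss(pred, gt, w) + dice_loss(pred, gt)
}

#' Gradient of the combined loss w.r.t. the predicted probabilities
#' @noRd
total_loss_grad <- function(pred, gt, w = NULL) {
  n <- length(pred)
  if (is.null(w)) w <- 1
  p <- clip(pred, .ce_eps, 1 - .ce_eps)
  d_ce <- -w * (gt / p - (1 - gt) / (1 - p)) / n
  num <- 2 * sum(pred * gt) + 1
  den <- sum(gt^2) + sum(pred^2) + 1
  d_dice <- (-2 * gt * den + 2 * pred * num) / den^2
  d_ce + d_dice
}
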