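# Evaluation statistics: pixel-wise segmentation metrics, Bland-Altman
# agreement with paired t-tests, and test-retest reliability (DSC, Cohen's
# kappa, ICC).
#
# Zero-denominator cases return NA markers rather than silent zeros, so
# averages over images are never corrupted by degenerate masks.

#' Pixel confusion counts between a predicted and a ground-truth mask
#'
#' Gland pixels are the positive class.
#'
#' @param pred,gt Binary 0/1 masks of identical shape.
#' @return List with `TP`, `FP`, `FN`, `TN` (their sum is the pixel count).
#' @export
confusion_counts <- function(pred, gt) {
  stop_if_shape_mismatch(pred, gt, "pred and gt")
  stopifnot(is_binary_mask(pred), is_binary_mask(gt))
  tp <- sum(pred == 1L & gt == 1L)
  fp <- sum(pred == 1L & gt == 0L)
  fn <- sum(pred == 0L & gt == 1L)
  list(TP = tp, FP = fp, FN = fn, TN = length(pred) - tp - fp - fn)
}

#' Precision, recall and F1 from confusion counts
#'
#' `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`; any vanishing
#' denominator yields `NA`.
#'
#' @param counts List from [confusion_counts()].
#' @return Named list `precision`, `recall`, `f1`.
#' @export
precision_recall_f1 <- function(counts) {
  p <- if (counts$TP + counts$FP == 0) NA_real_ else
    counts$TP / (counts$TP + counts$FP)
  r <- if (counts$TP + counts$FN == 0) NA_real_ else
    counts$TP / (counts$TP + counts$FN)
  f1 <- if (is.na(p) || is.na(r) || p + r == 0) NA_real_ else
    2 * p * r / (p + r)
  list(precision = p, recall = r, f1 = f1)
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A∩B| / (|A| + |B|)`; two empty masks agree perfectly (1).
#'
#' @param a,b Binary 0/1 masks of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dice_coefficient <- function(a, b) {
  stop_if_shape_mismatch(a, b, "masks")
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

#' Area under the pixel-level ROC curve
#'
#' Computed via the rank (Mann-Whitney) statistic with midrank tie
#' handling, equivalent to trapezoidal integration of the ROC curve over
#' all thresholds.
#'
#' @param prob Probability map.
#' @param gt Binary 0/1 mask of identical shape.
#' @return AUC in \[0, 1\]; `NA` if `gt` contains a single class.
#' @export
roc_auc <- function(prob, gt) {
  stop_if_shape_mismatch(prob, gt, "prob and gt")
  n1 <- sum(gt == 1L); n0 <- sum(gt == 0L)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(as.numeric(prob))  # midranks for ties
  (sum(r[gt == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bland-Altman agreement analysis of paired measurements
#'
#' Differences `d_i = manual_i - auto_i`; reports their mean and SD (n-1
#' denominator), the limits of agreement `mean +/- 1.96 SD`, 95% confidence
#' intervals for the mean (`SE = sd/sqrt(n)`) and for each limit
#' (`SE = sd * sqrt(3/n)`) using t quantiles with n-1 df, the fraction of
#' differences inside the limits, and the two-sided paired t-test p-value.
#'
#' @param manual,auto Paired numeric vectors of equal length >= 3.
#' @return A `bland_altman` list.
#' @export
bland_altman <- function(manual, auto) {
  if (length(manual) != length(auto)) stop("unpaired inputs", call. = FALSE)
  n <- length(manual)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  d <- manual - auto
  m <- mean(d); s <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  loa_up <- m + 1.96 * s; loa_lo <- m - 1.96 * s
  se_loa <- s * sqrt(3 / n)
  p <- if (s == 0) {
    if (m == 0) NA_real_ else 0
  } else {
    stats::t.test(manual, auto, paired = TRUE)$p.value
  }
  structure(list(
    n = n, mean_diff = m, sd_diff = s,
    loa_lower = loa_lo, loa_upper = loa_up,
    ci_mean = m + c(-1, 1) * tq * s / sqrt(n),
    ci_loa_lower = loa_lo + c(-1, 1) * tq * se_loa,
    ci_loa_upper = loa_up + c(-1, 1) * tq * se_loa,
    fraction_within_loa = mean(d >= loa_lo & d <= loa_up),
    p_value_paired_t = p), class = "bland_altman")
}

#' Bland-Altman plot (mean line, dotted limits of agreement, 95% CI band)
#'
#' @param manual,auto Paired numeric vectors.
#' @param title Plot title.
#' @return A ggplot object (requires the ggplot2 package).
#' @export
plot_bland_altman <- function(manual, auto, title = "Bland-Altman") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
  ba <- bland_altman(manual, auto)
  df <- data.frame(avg = (manual + auto) / 2, diff = manual - auto)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = ba$ci_mean[1], ymax = ba$ci_mean[2],
                      alpha = 0.3, fill = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = ba$mean_diff) +
    ggplot2::geom_hline(yintercept = c(ba$loa_lower, ba$loa_upper),
                        linetype = "dotted") +
    ggplot2::labs(title = title, x = "Mean of methods",
                  y = "Difference (manual - auto)")
}

#' Cohen's kappa between two binary masks
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` over the 2x2 pixel contingency table,
#' with expected agreement from the marginal products. Returns `NA` when
#' `p_e = 1` (both masks constant).
#'
#' @param a,b Binary 0/1 masks of identical shape.
#' @return Scalar in \[-1, 1\] or `NA`.
#' @export
cohens_kappa <- function(a, b) {
  stop_if_shape_mismatch(a, b, "masks")
  n <- length(a)
  n11 <- sum(a == 1L & b == 1L); n00 <- sum(a == 0L & b == 0L)
  pa1 <- sum(a == 1L) / n; pb1 <- sum(b == 1L) / n
  po <- (n11 + n00) / n
  pe <- pa1 * pb1 + (1 - pa1) * (1 - pb1)
  if (pe >= 1) return(NA_real_)
  (po - pe) / (1 - pe)
}

#' Intraclass correlation coefficient for two paired raters
#'
#' Default `type = "ICC2"`: two-way random effects, absolute agreement,
#' single measurement — ICC(2,1) from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`. `type = "ICC3"`
#' gives the consistency form ICC(3,1) `(MSR - MSE) / (MSR + (k-1) MSE)`,
#' which does not penalize a constant offset.
#'
#' @param values_a,values_b Paired numeric vectors of equal length >= 3.
#' @param type `"ICC2"` (absolute agreement) or `"ICC3"` (consistency).
#' @return Scalar in \[-1, 1\]; `NA` when the total variance is zero.
#' @export
icc <- function(values_a, values_b, type = c("ICC2", "ICC3")) {
  type <- match.arg(type)
  if (length(values_a) != length(values_b)) {
    stop("unpaired inputs", call. = FALSE)
  }
  n <- length(values_a)
  if (n < 3) stop("need at least 3 pairs", call. = FALSE)
  x <- cbind(values_a, values_b)
  k <- 2
  grand <- mean(x)
  if (all(x == grand)) return(NA_real_)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((x - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (type == "ICC3") {
    denom <- msr + (k - 1) * mse
    if (denom == 0) return(NA_real_)
    return((msr - mse) / denom)
  }
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (denom == 0) return(NA_real_)
  (msr - mse) / denom
}

#' Test-retest reliability report between two segmentation runs
#'
#' Per-image DSC and Cohen's kappa on paired masks (reported mean +/- sd)
#' and the ICC of the paired per-image gland counts, assembled per eyelid
#' side as in clinical repeatability tables.
#'
#' @param masks_run1,masks_run2 Paired lists of binary masks.
#' @param morph1,morph2 Paired lists of `eyelid_morphometry` summaries (or
#'   `NULL` to skip the ICC).
#' @param mode Label: `"intra-method"` (two automatic runs) or
#'   `"intra-observer"` (two manual annotations).
#' @return An `agreement_report` list with `dsc`, `kappa` (each
#'   `c(mean, sd)`), `icc`, `per_image` and `mode`.
#' @export
test_retest_report <- function(masks_run1, masks_run2, morph1 = NULL,
                               morph2 = NULL,
                               mode = c("intra-method", "intra-observer")) {
  mode <- match.arg(mode)
  if (length(masks_run1) != length(masks_run2)) {
    stop("unpaired mask lists", call. = FALSE)
  }
  dscs <- mapply(dice_coefficient, masks_run1, masks_run2)
  kaps <- mapply(cohens_kappa, masks_run1, masks_run2)
  icc_counts <- NA_real_
  if (!is.null(morph1)) {
    if (length(morph1) != length(morph2)) {
      stop("unpaired morphometry lists", call. = FALSE)
    }
    c1 <- vapply(morph1, function(m) as.numeric(m$gland_count), 0)
    c2 <- vapply(morph2, function(m) as.numeric(m$gland_count), 0)
    icc_counts <- if (all(c1 == c2)) 1 else icc(c1, c2)
  }
  sd0 <- function(v) if (length(v) > 1) stats::sd(v) else 0
  structure(list(
    dsc = c(mean = mean(dscs), sd = sd0(dscs)),
    kappa = c(mean = mean(kaps), sd = sd0(kaps)),
    icc = icc_counts,
    per_image = data.frame(image = seq_along(dscs), dsc = dscs,
                           kappa = kaps),
    mode = mode), class = "agreement_report")
}
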