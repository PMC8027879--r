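# Evaluation statistics: confusion counts, precision/recall/F1, Dice, AUC,
# Bland-Altman, kappa, ICC, test-retest reports.

random_mask <- function(h = 8, w = 8, p = 0.5) matrix(rbinom(h * w, 1, p), h, w)

test_that("confusion counts match a per-pixel loop oracle", {
  set.seed(3)
  for (rep in 1:10) {
    pred <- random_mask(); gt <- random_mask()
    cc <- confusion_counts(pred, gt)
    tp <- fp <- fn <- tn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == 1 && gt[i] == 1) tp <- tp + 1
      else if (pred[i] == 1) fp <- fp + 1
      else if (gt[i] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
    expect_equal(unlist(cc), c(TP = tp, FP = fp, FN = fn, TN = tn))
    expect_equal(sum(unlist(cc)), length(pred))
  }
  gt <- random_mask()
  expect_equal(confusion_counts(gt, gt)$FP, 0)
  expect_equal(confusion_counts(gt, gt)$FN, 0)
  comp <- confusion_counts(1L - gt, gt)
  expect_equal(comp$TP, 0)
  expect_equal(comp$TN, 0)
})

test_that("precision/recall/F1 follow their closed forms and NA conventions", {
  r <- precision_recall_f1(list(TP = 3, FP = 1, FN = 3, TN = 10))
  expect_equal(r$precision, 0.75)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 0.6)

  set.seed(4)
  for (rep in 1:1000) {
    tp <- sample(0:20, 1); fp <- sample(0:20, 1); fn <- sample(0:20, 1)
    r <- precision_recall_f1(list(TP = tp, FP = fp, FN = fn, TN = 5))
    if (!is.na(r$f1)) {
      expect_equal(r$f1, 2 * tp / (2 * tp + fp + fn), tolerance = 1e-12)
      if (abs(r$precision - r$recall) < 1e-12) expect_equal(r$f1, r$precision)
    }
  }
  z <- precision_recall_f1(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true(is.na(z$precision) && is.na(z$f1))
  expect_equal(z$recall, 0)
})

test_that("Dice equals F1 on binary masks and handles the empty case", {
  set.seed(5)
  for (rep in 1:30) {
    a <- random_mask(10, 10, 0.4); b <- random_mask(10, 10, 0.6)
    f1 <- precision_recall_f1(confusion_counts(a, b))$f1
    if (!is.na(f1)) {
      expect_equal(dice_coefficient(a, b), f1, tolerance = 1e-12)
    }
    expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  }
  a <- random_mask()
  expect_equal(dice_coefficient(a, a), 1)
  d <- matrix(0L, 4, 4); d[1:2, ] <- 1L
  expect_equal(dice_coefficient(d, 1L - d), 0)
  e <- matrix(0L, 4, 4)
  expect_equal(dice_coefficient(e, e), 1)
})

test_that("rank AUC equals the exhaustive threshold-sweep trapezoid", {
  perfect_gt <- matrix(c(rep(0L, 50), rep(1L, 50)), 10, 10)
  perfect_prob <- matrix(c(runif(50, 0, 0.4), runif(50, 0.6, 1)), 10, 10)
  expect_equal(roc_auc(perfect_prob, perfect_gt), 1)
  expect_equal(roc_auc(matrix(0.3, 10, 10), perfect_gt), 0.5)
  expect_true(is.na(roc_auc(perfect_prob, matrix(1L, 10, 10))))

  set.seed(6)
  for (rep in 1:10) {
    gt <- random_mask(10, 10, 0.35)
    prob <- matrix(round(runif(100), 2), 10, 10)  # coarse grid forces ties
    expect_equal(roc_auc(prob, gt), oracle_auc(prob, gt), tolerance = 1e-10)
  }
})

test_that("Bland-Altman reports mean, limits, CIs and paired-t correctly", {
  x <- c(10, 12, 9, 14, 11)
  ba0 <- bland_altman(x, x)
  expect_equal(ba0$mean_diff, 0)
  expect_equal(ba0$sd_diff, 0)
  expect_equal(ba0$loa_upper - ba0$loa_lower, 0)
  expect_equal(ba0$fraction_within_loa, 1)

  ba2 <- bland_altman(x + 2, x)
  expect_equal(ba2$mean_diff, 2)
  expect_equal(ba2$sd_diff, 0)

  set.seed(8)
  a <- rnorm(30, 10); b <- a + rnorm(30, 0.3, 0.5)
  ba <- bland_altman(a, b)
  d <- a - b
  expect_equal(ba$mean_diff, mean(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$p_value_paired_t, t.test(a, b, paired = TRUE)$p.value)
  expect_true(ba$loa_lower <= ba$mean_diff && ba$mean_diff <= ba$loa_upper)
  expect_error(bland_altman(1:5, 1:4), "unpaired")
  expect_error(bland_altman(1:2, 2:3), "at least 3")
})

test_that("limits of agreement cover ~95% of Gaussian differences", {
  set.seed(9)
  cover <- replicate(200, {
    a <- rnorm(50); b <- a + rnorm(50, 0, 1)
    bland_altman(a, b)$fraction_within_loa
  })
  expect_lt(abs(mean(cover) - 0.95), 0.03)
})

test_that("Cohen's kappa matches the contingency formula and its edge cases", {
  a <- random_mask(16, 16)
  expect_equal(cohens_kappa(a, a), 1)
  bal <- matrix(c(rep(0L, 128), rep(1L, 128)), 16, 16)
  expect_equal(cohens_kappa(bal, 1L - bal), -1)
  expect_true(is.na(cohens_kappa(matrix(1L, 4, 4), matrix(1L, 4, 4))))

  set.seed(10)
  for (rep in 1:10) {
    m1 <- random_mask(16, 16, 0.4); m2 <- random_mask(16, 16, 0.5)
    expect_equal(cohens_kappa(m1, m2), oracle_kappa(m1, m2),
                 tolerance = 1e-12)
    expect_equal(cohens_kappa(m1, m2), cohens_kappa(m2, m1))
    # invariant to consistently relabeling both masks
    expect_equal(cohens_kappa(1L - m1, 1L - m2), cohens_kappa(m1, m2),
                 tolerance = 1e-12)
  }
})

test_that("ICC(2,1) matches the ANOVA oracle and penalizes offsets", {
  v <- c(3, 5, 7, 9, 11)
  expect_equal(icc(v, v), 1)
  expect_lt(icc(v, v + 2), 1)              # absolute agreement
  expect_equal(icc(v, v + 2, type = "ICC3"), 1)  # consistency ignores offset

  set.seed(12)
  for (rep in 1:5) {
    a <- rnorm(15, 10, 3); b <- a + rnorm(15, 0.5, 1)
    expect_equal(icc(a, b), oracle_icc2(a, b), tolerance = 1e-10)
  }
  expect_true(is.na(icc(rep(1, 5), rep(1, 5))))
  expect_error(icc(1:5, 1:4), "unpaired")
})

test_that("test-retest reports perfect agreement for identical runs", {
  set.seed(13)
  masks <- lapply(1:5, function(i) random_mask(12, 12, 0.4))
  morph <- lapply(1:5, function(i) {
    structure(list(gland_count = i + 2L), class = "eyelid_morphometry")
  })
  rep0 <- test_retest_report(masks, masks, morph, morph)
  expect_equal(unname(rep0$dsc), c(1, 0))
  expect_equal(unname(rep0$kappa), c(1, 0))
  expect_equal(rep0$icc, 1)

  # flipping 1% of pixels breaks strict agreement
  masks2 <- lapply(masks, function(m) {
    i <- sample(length(m), 2)
    m[i] <- 1L - m[i]
    m
  })
  rep1 <- test_retest_report(masks, masks2)
  expect_lt(rep1$dsc[["mean"]], 1)
  expect_lt(rep1$kappa[["mean"]], 1)

  single <- test_retest_report(masks[1], masks[1])
  expect_equal(single$dsc[["sd"]], 0)
  expect_error(test_retest_report(masks, masks[1:3]), "unpaired")
})
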