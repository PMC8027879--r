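# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use plain loops / exhaustive search so they share no code
# with the implementation paths they check.

# A 64x64 phantom configuration used for the CPU-scale training tests:
# fewer, shorter glands so a small network trains in seconds.
phantom_config_small <- function(seed = 1L, clean = FALSE) {
  phantom_config(
    image_height = 64L, image_width = 64L, gland_count = 4L,
    length_range = c(40, 54), half_width_range = c(2L, 3L),
    amplitude_range = c(0.5, 1.5), wavelength_range = c(20, 40),
    margin = 3L,
    blur_sigma = if (clean) 0 else 0.8,
    specular_spot_count = if (clean) 0L else 1L,
    illumination_gradient_strength = if (clean) 0 else 0.2,
    noise_sigma = if (clean) 0 else 6,
    seed = seed)
}

# Default-scale generator with every artifact disabled (exact two-valued
# images, masks untouched).
phantom_config_clean <- function(seed = 1L, ...) {
  phantom_config(blur_sigma = 0, specular_spot_count = 0L,
                 illumination_gradient_strength = 0, noise_sigma = 0,
                 seed = seed, ...)
}

# BFS flood-fill component count (8-connectivity), queue-based.
oracle_component_count <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  seen <- matrix(FALSE, h, w)
  count <- 0L
  for (sr in seq_len(h)) for (sc in seq_len(w)) {
    if (mask[sr, sc] == 1L && !seen[sr, sc]) {
      count <- count + 1L
      queue <- list(c(sr, sc)); seen[sr, sc] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dy in -1:1) for (dx in -1:1) {
          y <- p[1] + dy; x <- p[2] + dx
          if (y >= 1 && y <= h && x >= 1 && x <= w &&
              mask[y, x] == 1L && !seen[y, x]) {
            seen[y, x] <- TRUE
            queue[[length(queue) + 1L]] <- c(y, x)
          }
        }
      }
    }
  }
  count
}

# All-pairs geodesic on a skeleton via Floyd-Warshall over its pixel graph.
oracle_longest_geodesic <- function(skel) {
  pts <- which(skel == 1L, arr.ind = TRUE)
  n <- nrow(pts)
  d <- matrix(Inf, n, n); diag(d) <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    dr <- abs(pts[i, 1] - pts[j, 1]); dc <- abs(pts[i, 2] - pts[j, 2])
    if (i != j && dr <= 1 && dc <= 1) d[i, j] <- sqrt(dr + dc)
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  }
  # endpoints: degree-1 pixels
  adj <- sapply(seq_len(n), function(i)
    sum(abs(pts[, 1] - pts[i, 1]) <= 1 & abs(pts[, 2] - pts[i, 2]) <= 1) - 1L)
  ends <- which(adj == 1L)
  if (length(ends) == 0L) ends <- seq_len(n)
  max(d[ends, ends][is.finite(d[ends, ends])])
}

# Element-by-element loss oracles.
oracle_ce <- function(pred, gt, w = NULL) {
  if (is.null(w)) w <- pred * 0 + 1
  eps <- 1e-7
  total <- 0
  for (i in seq_along(pred)) {
    p <- min(max(pred[i], eps), 1 - eps)
    total <- total - w[i] * (gt[i] * log(p) + (1 - gt[i]) * log(1 - p))
  }
  total / length(pred)
}

oracle_dice_loss <- function(pred, gt, smooth = 1) {
  num <- 0; dg <- 0; dp <- 0
  for (i in seq_along(pred)) {
    num <- num + pred[i] * gt[i]
    dg <- dg + gt[i]^2
    dp <- dp + pred[i]^2
  }
  1 - (2 * num + smooth) / (dg + dp + smooth)
}

# Threshold-sweep trapezoidal ROC AUC.
oracle_auc <- function(prob, gt) {
  p <- as.numeric(prob); g <- as.numeric(gt)
  ths <- c(Inf, sort(unique(p), decreasing = TRUE), -Inf)
  tpr <- fpr <- numeric(length(ths))
  for (i in seq_along(ths)) {
    pos <- p >= ths[i]
    tpr[i] <- sum(pos & g == 1) / sum(g == 1)
    fpr[i] <- sum(pos & g == 0) / sum(g == 0)
  }
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# 2x2 contingency-table kappa.
oracle_kappa <- function(a, b) {
  n <- length(a)
  tab <- table(factor(a, 0:1), factor(b, 0:1)) / n
  po <- tab[1, 1] + tab[2, 2]
  pe <- sum(tab[1, ]) * sum(tab[, 1]) + sum(tab[2, ]) * sum(tab[, 2])
  (po - pe) / (1 - pe)
}

# ICC(2,1) via aov() mean squares — independent ANOVA route.
oracle_icc2 <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + rater, data = df))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

# Independent Riemann-sum arc length of a sinusoidal centerline.
oracle_arc_length <- function(spec, dy = 1e-3) {
  y <- seq(spec$top_row, spec$bottom_row, by = dy)
  om <- 2 * pi / spec$wavelength
  slope <- spec$amplitude * om * cos(om * (y - spec$top_row) + spec$phase)
  f <- sqrt(1 + slope^2)
  sum((utils::head(f, -1) + utils::tail(f, -1)) / 2) * dy
}

# Thick semicircular band mask (right half-plane), for tortuosity checks.
semicircle_band_mask <- function(r, hw) {
  n <- 2L * r + 2L * hw + 10L
  cy <- cx <- n %/% 2L
  rows <- matrix(rep(seq_len(n), n), n, n)
  cols <- matrix(rep(seq_len(n), each = n), n, n)
  rad <- sqrt((rows - cy)^2 + (cols - cx)^2)
  (abs(rad - r) <= hw & cols >= cx) + 0L
}
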