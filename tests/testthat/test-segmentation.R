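# Losses, network contracts, k-fold protocol, training behaviour,
# inference determinism.

test_that("cross-entropy and Dice losses match brute-force oracles", {
  set.seed(42)
  for (rep in 1:20) {
    pred <- matrix(runif(16), 4, 4)
    gt <- matrix(rbinom(16, 1, 0.5), 4, 4)
    w <- matrix(runif(16, 0.5, 2), 4, 4)
    expect_equal(ce_loss(pred, gt), oracle_ce(pred, gt), tolerance = 1e-10)
    expect_equal(ce_loss(pred, gt, w), oracle_ce(pred, gt, w),
                 tolerance = 1e-10)
    expect_equal(dice_loss(pred, gt), oracle_dice_loss(pred, gt),
                 tolerance = 1e-10)
    expect_identical(total_loss(pred, gt, w),
                     ce_loss(pred, gt, w) + dice_loss(pred, gt))
  }
})

test_that("losses take their closed-form values on canonical inputs", {
  gt <- matrix(rbinom(64, 1, 0.4), 8, 8)
  expect_equal(ce_loss(matrix(0.5, 8, 8), gt), log(2), tolerance = 1e-12)
  # perfect prediction: loss only reflects the clipping epsilon
  expect_lt(ce_loss(gt, gt), 1e-5)
  expect_equal(dice_loss(gt, gt), 0)
  disjoint_a <- matrix(0, 8, 8); disjoint_a[, 1:4] <- 1
  disjoint_b <- 1 - disjoint_a
  expect_gt(dice_loss(disjoint_a, disjoint_b), 0.95)
  empty <- matrix(0, 8, 8)
  expect_equal(dice_loss(empty, empty), 0)  # smoothing defines empty-empty
  expect_error(ce_loss(matrix(0.5, 4, 4), matrix(0L, 5, 5)), "shape")
})

test_that("model construction honors shape, range, seed and backbone contracts", {
  cfg <- train_config(input_size = c(32L, 32L), depth = 2L,
                      base_channels = 4L, seed = 9L)
  m1 <- build_unet(cfg)
  m2 <- build_unet(cfg)
  expect_identical(m1$params, m2$params)

  x <- matrix(runif(32 * 32), ncol = 1)
  out <- meibomorph:::unet_forward(m1, x, 32L, 32L)$prob
  expect_equal(dim(out), c(1024L, 1L))
  expect_true(all(out >= 0 & out <= 1))

  # size-agnostic: any multiple of 2^depth works
  x64 <- matrix(runif(64 * 64), ncol = 1)
  out64 <- meibomorph:::unet_forward(m1, x64, 64L, 64L)$prob
  expect_equal(nrow(out64), 64L * 64L)

  expect_error(train_config(input_size = c(60L, 60L), depth = 3L),
               "divisible")
  expect_error(build_unet(train_config(encoder = "inception-resnet-v2",
                                       input_size = c(32L, 32L))),
               "plain")
})

test_that("k-fold split partitions ids with balanced sizes", {
  folds <- kfold_split(seq_len(628), 5, seed = 1L)
  val_sizes <- sort(vapply(folds, function(f) length(f$val), 0L))
  expect_identical(val_sizes, c(125L, 125L, 126L, 126L, 126L))
  for (f in folds) {
    expect_length(intersect(f$train, f$val), 0L)
    expect_setequal(c(f$train, f$val), seq_len(628))
    if (length(f$val) == 126L) expect_length(f$train, 502L)
  }
  all_val <- unlist(lapply(folds, `[[`, "val"))
  expect_setequal(all_val, seq_len(628))
  expect_length(all_val, 628L)

  loo <- kfold_split(letters[1:10], 10, seed = 2L)
  expect_true(all(vapply(loo, function(f) length(f$val), 0L) == 1L))
  expect_error(kfold_split(1:10, 1), "k")
  expect_error(kfold_split(1:10, 11), "k")
  expect_identical(kfold_split(1:50, 5, seed = 3L),
                   kfold_split(1:50, 5, seed = 3L))
})

test_that("training reduces validation loss, is seeded, and logs stages", {
  train_s <- simulate_phantoms(phantom_config_small(1L), 10L, seed = 1L)
  val_s <- simulate_phantoms(phantom_config_small(1L), 4L, seed = 51L)
  shrink <- function(s) lapply(s, function(p) list(
    image = p$image[seq(1, 64, by = 2), seq(1, 64, by = 2)],
    mask = p$mask[seq(1, 64, by = 2), seq(1, 64, by = 2)]))
  tr <- shrink(train_s); va <- shrink(val_s)
  cfg <- train_config(epochs = 4L, batch_size = 5L, learning_rate = 3e-3,
                      input_size = c(32L, 32L), depth = 2L,
                      base_channels = 4L, seed = 5L)
  run <- function() {
    m <- build_unet(cfg)
    train_unet(m, lapply(tr, `[[`, "image"), lapply(tr, `[[`, "mask"),
               val_images = lapply(va, `[[`, "image"),
               val_masks = lapply(va, `[[`, "mask"))
  }
  m1 <- run()
  expect_lt(tail(m1$history$val_loss, 1), m1$history$val_loss[1])
  expect_equal(nrow(m1$history), 4L)
  m2 <- run()
  expect_identical(tail(m1$history$train_loss, 1),
                   tail(m2$history$train_loss, 1))

  # two-stage transfer bookkeeping: pretrain epochs precede main epochs
  cfg2 <- cfg
  cfg2$epochs <- 2L
  cfg2$pretrain <- list(images = lapply(tr[1:3], `[[`, "image"),
                        masks = lapply(tr[1:3], `[[`, "mask"),
                        epochs = 2L)
  m3 <- train_unet(build_unet(cfg2), lapply(tr, `[[`, "image"),
                   lapply(tr, `[[`, "mask"))
  expect_equal(nrow(m3$history), 4L)
  expect_identical(m3$history$stage, c("pretrain", "pretrain", "main", "main"))

  expect_error(train_unet(build_unet(cfg), list(), list()), "empty")
})

test_that("prediction preserves native resolution and is bitwise repeatable", {
  cfg <- train_config(input_size = c(32L, 32L), depth = 2L,
                      base_channels = 4L, seed = 2L)
  m <- build_unet(cfg)
  img <- matrix(runif(48 * 40), 48, 40)
  p1 <- predict(m, img)
  expect_equal(dim(p1), c(48L, 40L))
  expect_true(all(p1 >= 0 & p1 <= 1))
  expect_identical(p1, predict(m, img))
  expect_identical(binarize(p1), binarize(predict(m, img)))

  expect_true(all(is.finite(predict(m, matrix(0, 32, 32)))))
  expect_true(all(is.finite(predict(m, matrix(1, 32, 32)))))
  expect_error(predict(m, array(runif(32 * 32 * 3), c(32, 32, 3))), "color")
})

test_that("binarization is thresholded and monotone", {
  p <- matrix(0.7, 4, 4)
  expect_true(all(binarize(p, 0.5) == 1L))
  expect_true(all(binarize(p, 0.9) == 0L))
  set.seed(1)
  pr <- matrix(runif(100), 10, 10)
  prev <- binarize(pr, 0.05)
  for (th in c(0.25, 0.5, 0.75, 0.95)) {
    cur <- binarize(pr, th)
    expect_true(all(cur <= prev))  # foreground shrinks as threshold rises
    prev <- cur
  }
})
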