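# Training (Adam on the combined CE + Dice objective), inference and the
# k-fold cross-validation protocol.

zero_like <- function(params) lapply(params, function(p) p * 0)

adam_state <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Prepare an image/mask pair at the network resolution
#' @noRd
prep_pair <- function(image, mask, input_size) {
  if (max(image) > 1.5) image <- image / 255
  img <- resize_matrix(image, input_size[1], input_size[2], "bilinear")
  msk <- NULL
  if (!is.null(mask)) {
    if (!is_binary_mask(mask)) stop("mask must be binary 0/1", call. = FALSE)
    stop_if_shape_mismatch(image, mask, "image and mask")
    msk <- resize_matrix(mask, input_size[1], input_size[2], "none")
  }
  list(x = matrix(as.numeric(img), ncol = 1L), g = as.numeric(msk))
}

#' Train the segmentation network
#'
#' Optimizes the combined cross-entropy + Dice loss with Adam. Images are
#' resized to `config$input_size` (bilinear) and masks with nearest
#' neighbour so they stay binary. When `config$pretrain` is given (a list
#' with `images`, `masks`, `epochs`), that auxiliary stage runs first and
#' the optimizer then continues on the target set — the two-stage transfer
#' protocol. Shuffling is seeded; the whole procedure is deterministic for
#' a fixed config.
#'
#' @param model A [build_unet()] model.
#' @param images List of grayscale matrices (0-1 or 0-255 scale).
#' @param masks List of binary masks matching `images`.
#' @param val_images,val_masks Optional validation pairs; per-epoch
#'   validation loss and hard Dice (threshold `config$binarize_threshold`)
#'   are recorded in the history.
#' @param verbose Print per-epoch progress.
#' @return The model with trained parameters and a `history` data frame
#'   (`stage`, `epoch`, `train_loss`, `val_loss`, `val_dice`).
#' @export
train_unet <- function(model, images, masks, val_images = NULL,
                       val_masks = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  config <- model$config
  if (length(images) == 0L) stop("empty training set", call. = FALSE)
  if (length(images) != length(masks)) {
    stop("images and masks differ in length", call. = FALSE)
  }
  insz <- config$input_size
  pairs <- mapply(function(i, m) prep_pair(i, m, insz),
                  images, masks, SIMPLIFY = FALSE)
  vpairs <- NULL
  if (!is.null(val_images)) {
    vpairs <- mapply(function(i, m) prep_pair(i, m, insz),
                     val_images, val_masks, SIMPLIFY = FALSE)
  }
  stages <- list()
  if (!is.null(config$pretrain)) {
    pp <- mapply(function(i, m) prep_pair(i, m, insz),
                 config$pretrain$images, config$pretrain$masks,
                 SIMPLIFY = FALSE)
    stages$pretrain <- list(pairs = pp, epochs = config$pretrain$epochs)
  }
  stages$main <- list(pairs = pairs, epochs = config$epochs)

  params <- model$params
  st <- adam_state(params)
  hist <- list()
  with_seed(config$seed + 1L, {
    for (stage_name in names(stages)) {
      stage <- stages[[stage_name]]
      n <- length(stage$pairs)
      for (epoch in seq_len(stage$epochs)) {
        ord <- sample.int(n)
        batch_losses <- c()
        for (b0 in seq(1L, n, by = config$batch_size)) {
          ids <- ord[b0:min(b0 + config$batch_size - 1L, n)]
          grads <- zero_like(params)
          bloss <- 0
          for (id in ids) {
            pr <- stage$pairs[[id]]
            model$params <- params
            fw <- unet_forward(model, pr$x, insz[1], insz[2],
                               want_cache = TRUE)
            p <- as.numeric(fw$prob)
            bloss <- bloss + total_loss(p, pr$g)
            dp <- matrix(total_loss_grad(p, pr$g) / length(ids), ncol = 1L)
            grads <- unet_backward(model, fw$cache, fw$prob, dp, grads)
          }
          up <- adam_step(params, grads, st, config$learning_rate)
          params <- up$params
          st <- up$state
          batch_losses <- c(batch_losses, bloss / length(ids))
        }
        vl <- NA_real_; vd <- NA_real_
        if (!is.null(vpairs)) {
          model$params <- params
          vls <- vds <- numeric(length(vpairs))
          for (k in seq_along(vpairs)) {
            pr <- vpairs[[k]]
            p <- as.numeric(unet_forward(model, pr$x, insz[1], insz[2])$prob)
            vls[k] <- total_loss(p, pr$g)
            pm <- as.integer(p >= config$binarize_threshold)
            vds[k] <- (2 * sum(pm * pr$g) + 1) / (sum(pm) + sum(pr$g) + 1)
          }
          vl <- mean(vls); vd <- mean(vds)
        }
        hist[[length(hist) + 1L]] <- data.frame(
          stage = stage_name, epoch = epoch,
          train_loss = mean(batch_losses), val_loss = vl, val_dice = vd)
        if (verbose) {
          message(sprintf("[%s] epoch %d/%d train_loss=%.4f val_loss=%.4f val_dice=%.4f",
                          stage_name, epoch, stage$epochs,
                          mean(batch_losses), vl, vd))
        }
      }
    }
  })
  model$params <- params
  model$history <- do.call(rbind, hist)
  model
}

#' Predict a gland probability map for an image of any size
#'
#' The image is resized (bilinear) to the network input size for the
#' forward pass and the probability map is resized back to the native
#' resolution, so downstream morphometry operates at the original pixel
#' grid. Inference is deterministic: the same image always yields the same
#' map.
#'
#' @param object A trained `unet_model`.
#' @param image Grayscale matrix, 0-1 or 0-255 scale. A 3-channel array is
#'   rejected unless `convert = TRUE`, which averages channels to luma.
#' @param convert Allow silent grayscale conversion of color input.
#' @param ... Unused.
#' @return Probability matrix with the dimensions of `image`, values in
#'   \[0, 1\].
#' @export
predict.unet_model <- function(object, image, convert = FALSE, ...) {
  if (length(dim(image)) == 3L) {
    if (!convert) {
      stop("color input: pass convert = TRUE to collapse to grayscale",
           call. = FALSE)
    }
    image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  }
  h0 <- nrow(image); w0 <- ncol(image)
  insz <- object$config$input_size
  pr <- prep_pair(image, NULL, insz)
  prob <- unet_forward(object, pr$x, insz[1], insz[2])$prob
  prob <- matrix(as.numeric(prob), insz[1], insz[2])
  clip(resize_matrix(prob, h0, w0, "bilinear"), 0, 1)
}

#' Threshold a probability map into a binary mask
#'
#' @param prob Probability matrix in \[0, 1\].
#' @param threshold Scalar in (0, 1); pixels with `prob >= threshold` become
#'   foreground.
#' @return Integer 0/1 matrix.
#' @export
binarize <- function(prob, threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  m <- (prob >= threshold) + 0L
  dim(m) <- dim(prob)
  m
}

#' Seeded k-fold split of item ids
#'
#' Randomly partitions `item_ids` into `k` validation folds whose sizes
#' differ by at most one; each id appears in exactly one validation fold
#' and the complementary ids form the training set of that fold.
#'
#' @param item_ids Vector of ids.
#' @param k Number of folds (`2 <= k <= length(item_ids)`).
#' @param seed Integer seed.
#' @return List of `k` lists with elements `train` and `val`.
#' @export
kfold_split <- function(item_ids, k, seed = 1L) {
  n <- length(item_ids)
  if (k < 2L || k > n) stop("need 2 <= k <= number of items", call. = FALSE)
  with_seed(seed, {
    ord <- sample(item_ids)
    sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
    ends <- cumsum(sizes)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    lapply(seq_len(k), function(i) {
      val <- ord[starts[i]:ends[i]]
      list(train = setdiff(item_ids, val), val = val)
    })
  })
}

#' Run the k-fold cross-validation protocol on an image/mask set
#'
#' Trains one fresh model per fold and records the per-fold validation Dice
#' from the final epoch.
#'
#' @param images,masks Paired lists.
#' @param config A [train_config()]; `config$k_folds` folds are used.
#' @return Data frame with one row per fold: `fold`, `n_train`, `n_val`,
#'   `val_dice`.
#' @export
crossval_unet <- function(images, masks, config) {
  folds <- kfold_split(seq_along(images), config$k_folds, config$seed)
  out <- lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    m <- build_unet(config)
    m <- train_unet(m, images[f$train], masks[f$train],
                    val_images = images[f$val], val_masks = masks[f$val])
    data.frame(fold = i, n_train = length(f$train), n_val = length(f$val),
               val_dice = utils::tail(m$history$val_dice, 1L))
  })
  do.call(rbind, out)
}
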