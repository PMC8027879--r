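# A small plain U-Net implemented directly on matrices.
#
# Feature maps at one resolution are stored as (H*W) x C matrices in R's
# column-major pixel order; 3x3 convolutions are evaluated as im2col patch
# matrices times a (9*Cin) x Cout weight matrix, so the heavy lifting is
# BLAS matrix multiplication. The geometry (neighbour indices, pooling
# indices) depends only on H and W and is memoized. Backpropagation mirrors
# the forward pass exactly, which keeps training fully deterministic for a
# fixed seed.

.geom_cache <- new.env(parent = emptyenv())

conv_idx <- function(h, w) {
  key <- sprintf("c%dx%d", h, w)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  hw <- h * w
  p <- seq_len(hw)
  row <- ((p - 1L) %% h) + 1L
  col <- ((p - 1L) %/% h) + 1L
  offs <- expand.grid(dy = -1:1, dx = -1:1)
  idx <- matrix(hw + 1L, hw, 9L)
  for (k in 1:9) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    ok <- row + dy >= 1L & row + dy <= h & col + dx >= 1L & col + dx <= w
    idx[ok, k] <- p[ok] + dy + dx * h
  }
  .geom_cache[[key]] <- idx
  idx
}

pool_idx <- function(h, w) {
  key <- sprintf("p%dx%d", h, w)
  if (!is.null(.geom_cache[[key]])) return(.geom_cache[[key]])
  hc <- h %/% 2L; wc <- w %/% 2L
  q <- seq_len(hc * wc)
  rc <- ((q - 1L) %% hc) + 1L
  cc <- ((q - 1L) %/% hc) + 1L
  i11 <- (2L * cc - 2L) * h + (2L * rc - 1L)
  p <- seq_len(h * w)
  rowf <- ((p - 1L) %% h) + 1L
  colf <- ((p - 1L) %/% h) + 1L
  up_map <- (ceiling(colf / 2) - 1L) * hc + ceiling(rowf / 2)
  out <- list(i = cbind(i11, i11 + 1L, i11 + h, i11 + h + 1L),
              up_map = up_map, hc = hc, wc = wc)
  .geom_cache[[key]] <- out
  out
}

im2col <- function(x, idx) {
  cin <- ncol(x)
  xp <- rbind(x, matrix(0, 1L, cin))
  p <- matrix(0, nrow(x), 9L * cin)
  for (k in 1:9) {
    p[, ((k - 1L) * cin + 1L):(k * cin)] <- xp[idx[, k], , drop = FALSE]
  }
  p
}

conv_fwd <- function(x, wt, b, idx) {
  p <- im2col(x, idx)
  y <- p %*% wt
  y <- y + rep(b, each = nrow(y))
  list(y = y, p = p)
}

conv_bwd <- function(dy, p, wt, idx, cin, hw) {
  dwt <- crossprod(p, dy)
  db <- colSums(dy)
  dp <- dy %*% t(wt)
  dx <- matrix(0, hw, cin)
  for (k in 1:9) {
    r <- idx[, k]
    ok <- r <= hw
    cols <- ((k - 1L) * cin + 1L):(k * cin)
    dx[r[ok], ] <- dx[r[ok], ] + dp[ok, cols, drop = FALSE]
  }
  list(dx = dx, dwt = dwt, db = db)
}

maxpool_fwd <- function(x, pi) {
  a1 <- x[pi$i[, 1], , drop = FALSE]; a2 <- x[pi$i[, 2], , drop = FALSE]
  a3 <- x[pi$i[, 3], , drop = FALSE]; a4 <- x[pi$i[, 4], , drop = FALSE]
  m <- pmax(a1, a2, a3, a4)
  s1 <- a1 == m; s2 <- (a2 == m) & !s1
  s3 <- (a3 == m) & !s1 & !s2; s4 <- !(s1 | s2 | s3)
  list(y = m, sel = list(s1, s2, s3, s4))
}

maxpool_bwd <- function(dm, sel, pi, hw_fine, cin) {
  dx <- matrix(0, hw_fine, cin)
  for (j in 1:4) dx[pi$i[, j], ] <- dm * sel[[j]]
  dx
}

#' Training / model configuration for the gland segmentation network
#'
#' @param epochs Training epochs on the target set.
#' @param batch_size Images per gradient step.
#' @param learning_rate Adam learning rate.
#' @param optimizer Only `"adam"` is supported.
#' @param binarize_threshold Probability threshold for [binarize()].
#' @param input_size `c(height, width)` the network operates at; inputs are
#'   resized to this (bilinear for images, nearest for masks) and
#'   predictions resized back. Must be divisible by `2^depth`.
#' @param k_folds Folds for the cross-validation protocol.
#' @param seed Seed controlling weight initialization and shuffling.
#' @param depth Number of down/up-sampling levels.
#' @param base_channels Channels of the first encoder block; doubled per
#'   level.
#' @param encoder `"plain"` for the built-in randomly initialized encoder. A
#'   pretrained backbone name may be given together with `encoder_weights`
#'   (a local weights file); without local weights an error instructs the
#'   plain fallback — weights are never downloaded.
#' @param encoder_weights Optional path to local backbone weights.
#' @param pretrain Optional pre-training stage run before the main stage:
#'   a list with elements `images`, `masks` (auxiliary dataset) and
#'   `epochs`.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 30L, batch_size = 5L, learning_rate = 1e-3,
                         optimizer = "adam", binarize_threshold = 0.5,
                         input_size = c(256L, 256L), k_folds = 5L, seed = 1L,
                         depth = 4L, base_channels = 8L,
                         encoder = "plain", encoder_weights = NULL,
                         pretrain = NULL) {
  optimizer <- match.arg(optimizer, "adam")
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0,
            binarize_threshold > 0, binarize_threshold < 1,
            k_folds >= 2, depth >= 1, base_channels >= 1,
            length(input_size) == 2)
  if (any(input_size %% (2L^depth) != 0L)) {
    stop("input_size must be divisible by 2^depth", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = optimizer,
                 binarize_threshold = binarize_threshold,
                 input_size = as.integer(input_size),
                 k_folds = as.integer(k_folds), seed = as.integer(seed),
                 depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 encoder = encoder, encoder_weights = encoder_weights,
                 pretrain = pretrain),
            class = "train_config")
}

unet_channels <- function(depth, base) {
  enc <- base * 2L^(seq_len(depth) - 1L)
  list(enc = enc, bottleneck = base * 2L^depth)
}

#' Build the segmentation model
#'
#' Constructs a plain U-Net: `depth` encoder blocks (two 3x3 conv + ReLU,
#' then 2x2 max-pool), a bottleneck, symmetric decoder blocks (nearest 2x
#' upsampling, skip concatenation, two 3x3 conv + ReLU) and a 1x1 sigmoid
#' head producing a per-pixel gland probability. He-normal initialization
#' seeded by `config$seed`.
#'
#' @param config A [train_config()].
#' @return A `unet_model` list with `params` and `config`.
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "train_config"))
  if (!identical(config$encoder, "plain")) {
    if (is.null(config$encoder_weights) || !file.exists(config$encoder_weights)) {
      stop(sprintf(paste0(
        "pretrained backbone '%s' requested but no local weights file is ",
        "available; weights are never downloaded - supply encoder_weights ",
        "or fall back to encoder = 'plain'"), config$encoder), call. = FALSE)
    }
    stop("loading external backbone weights is not implemented; use the ",
         "plain encoder", call. = FALSE)
  }
  ch <- unet_channels(config$depth, config$base_channels)
  params <- list()
  he <- function(fan_in, cout) {
    matrix(stats::rnorm(fan_in * cout, 0, sqrt(2 / fan_in)), fan_in, cout)
  }
  with_seed(config$seed, {
    cin <- 1L
    for (i in seq_len(config$depth)) {
      cout <- ch$enc[i]
      params[[sprintf("enc%da_W", i)]] <- he(9L * cin, cout)
      params[[sprintf("enc%da_b", i)]] <- numeric(cout)
      params[[sprintf("enc%db_W", i)]] <- he(9L * cout, cout)
      params[[sprintf("enc%db_b", i)]] <- numeric(cout)
      cin <- cout
    }
    params[["bota_W"]] <- he(9L * cin, ch$bottleneck)
    params[["bota_b"]] <- numeric(ch$bottleneck)
    params[["botb_W"]] <- he(9L * ch$bottleneck, ch$bottleneck)
    params[["botb_b"]] <- numeric(ch$bottleneck)
    up_ch <- ch$bottleneck
    for (i in rev(seq_len(config$depth))) {
      cat_ch <- up_ch + ch$enc[i]
      params[[sprintf("dec%da_W", i)]] <- he(9L * cat_ch, ch$enc[i])
      params[[sprintf("dec%da_b", i)]] <- numeric(ch$enc[i])
      params[[sprintf("dec%db_W", i)]] <- he(9L * ch$enc[i], ch$enc[i])
      params[[sprintf("dec%db_b", i)]] <- numeric(ch$enc[i])
      up_ch <- ch$enc[i]
    }
    params[["head_W"]] <- he(ch$enc[1], 1L)
    params[["head_b"]] <- numeric(1L)
  })
  structure(list(params = params, config = config), class = "unet_model")
}

conv_relu <- function(x, params, name, idx, cache, want_cache) {
  cf <- conv_fwd(x, params[[paste0(name, "_W")]],
                 params[[paste0(name, "_b")]], idx)
  act <- cf$y > 0
  y <- cf$y * act
  if (want_cache) {
    cache[[paste0(name, "_p")]] <- cf$p
    cache[[paste0(name, "_act")]] <- act
  }
  list(y = y, cache = cache)
}

#' Forward pass; returns probabilities and (optionally) the backprop cache
#' @noRd
unet_forward <- function(model, x_mat, h, w, want_cache = FALSE) {
  params <- model$params
  depth <- model$config$depth
  cache <- list(h = h, w = w)
  hs <- h; ws <- w
  x <- x_mat
  skips <- vector("list", depth)
  for (i in seq_len(depth)) {
    idx <- conv_idx(hs, ws)
    r <- conv_relu(x, params, sprintf("enc%da", i), idx, cache, want_cache)
    cache <- r$cache
    r <- conv_relu(r$y, params, sprintf("enc%db", i), idx, cache, want_cache)
    cache <- r$cache
    skips[[i]] <- r$y
    pi <- pool_idx(hs, ws)
    pf <- maxpool_fwd(r$y, pi)
    if (want_cache) cache[[sprintf("pool%d_sel", i)]] <- pf$sel
    x <- pf$y
    hs <- hs %/% 2L; ws <- ws %/% 2L
  }
  idx <- conv_idx(hs, ws)
  r <- conv_relu(x, params, "bota", idx, cache, want_cache)
  cache <- r$cache
  r <- conv_relu(r$y, params, "botb", idx, cache, want_cache)
  cache <- r$cache
  x <- r$y
  for (i in rev(seq_len(depth))) {
    hs <- hs * 2L; ws <- ws * 2L
    pi <- pool_idx(hs, ws)
    up <- x[pi$up_map, , drop = FALSE]
    x <- cbind(up, skips[[i]])
    if (want_cache) cache[[sprintf("cat%d_upch", i)]] <- ncol(up)
    idx <- conv_idx(hs, ws)
    r <- conv_relu(x, params, sprintf("dec%da", i), idx, cache, want_cache)
    cache <- r$cache
    r <- conv_relu(r$y, params, sprintf("dec%db", i), idx, cache, want_cache)
    cache <- r$cache
    x <- r$y
  }
  z <- x %*% params$head_W + rep(params$head_b, each = nrow(x))
  prob <- 1 / (1 + exp(-z))
  if (want_cache) cache$head_in <- x
  list(prob = prob, cache = cache)
}

conv_relu_bwd <- function(dy, params, name, idx, cache, hw, grads) {
  dy <- dy * cache[[paste0(name, "_act")]]
  wt <- params[[paste0(name, "_W")]]
  cin <- nrow(wt) %/% 9L
  cb <- conv_bwd(dy, cache[[paste0(name, "_p")]], wt, idx, cin, hw)
  grads[[paste0(name, "_W")]] <- grads[[paste0(name, "_W")]] + cb$dwt
  grads[[paste0(name, "_b")]] <- grads[[paste0(name, "_b")]] + cb$db
  list(dx = cb$dx, grads = grads)
}

#' Backward pass from d(loss)/d(prob); accumulates into `grads`
#'
#' Mirrors the forward pass: head, decoder blocks from full resolution down
#' to the bottleneck (splitting each concatenation into an upsample branch
#' and a stored skip gradient), then the encoder blocks from deepest to
#' shallowest, adding each skip gradient back in at its level.
#' @noRd
unet_backward <- function(model, cache, prob, dprob, grads) {
  params <- model$params
  depth <- model$config$depth
  h <- cache$h; w <- cache$w
  dz <- dprob * prob * (1 - prob)
  grads$head_W <- grads$head_W + crossprod(cache$head_in, dz)
  grads$head_b <- grads$head_b + colSums(dz)
  dx <- dz %*% t(params$head_W)
  dskips <- vector("list", depth)
  hs <- h; ws <- w
  for (i in seq_len(depth)) {        # dec_1 ran last in forward
    idx <- conv_idx(hs, ws)
    hw <- hs * ws
    r <- conv_relu_bwd(dx, params, sprintf("dec%db", i), idx, cache, hw, grads)
    grads <- r$grads
    r <- conv_relu_bwd(r$dx, params, sprintf("dec%da", i), idx, cache, hw, grads)
    grads <- r$grads
    upch <- cache[[sprintf("cat%d_upch", i)]]
    dskips[[i]] <- r$dx[, -seq_len(upch), drop = FALSE]
    pi <- pool_idx(hs, ws)
    dx <- rowsum(r$dx[, seq_len(upch), drop = FALSE], pi$up_map)
    hs <- hs %/% 2L; ws <- ws %/% 2L
  }
  idx <- conv_idx(hs, ws)
  hw <- hs * ws
  r <- conv_relu_bwd(dx, params, "botb", idx, cache, hw, grads)
  grads <- r$grads
  r <- conv_relu_bwd(r$dx, params, "bota", idx, cache, hw, grads)
  grads <- r$grads
  dx <- r$dx                          # gradient at pooled enc_depth output
  for (j in rev(seq_len(depth))) {
    hs <- h %/% 2L^(j - 1L); ws <- w %/% 2L^(j - 1L)
    pi <- pool_idx(hs, ws)
    denc <- maxpool_bwd(dx, cache[[sprintf("pool%d_sel", j)]],
                        pi, hs * ws, ncol(dx)) + dskips[[j]]
    idx <- conv_idx(hs, ws)
    r <- conv_relu_bwd(denc, params, sprintf("enc%db", j), idx, cache,
                       hs * ws, grads)
    grads <- r$grads
    r <- conv_relu_bwd(r$dx, params, sprintf("enc%da", j), idx, cache,
                       hs * ws, grads)
    grads <- r$grads
    dx <- r$dx                        # input gradient = pooled output j-1
  }
  grads
}
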