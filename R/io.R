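# Image and dataset I/O. PNG in and out (JPG is not written to avoid
# recompressing binary masks); masks are binarized on read.

#' Read a grayscale image from PNG
#'
#' Color images are collapsed to luma with a warning.
#'
#' @param path PNG file.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_gray_png <- function(path) {
  if (!file.exists(path)) stop("missing file: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    warning("color image converted to grayscale: ", path, call. = FALSE)
    x <- 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  }
  x
}

#' Read a binary mask from PNG (any nonzero pixel becomes 1)
#'
#' @param path PNG file.
#' @return Integer 0/1 matrix.
#' @export
read_mask_png <- function(path) {
  x <- read_gray_png(path)
  (x > 0) + 0L
}

#' Write a matrix in \[0, 1\] as 8-bit grayscale PNG
#'
#' @param x Numeric matrix, values in \[0, 1\] (binary masks included).
#' @param path Output file.
#' @export
write_gray_png <- function(x, path) {
  png::writePNG(clip(x, 0, 1), path)
  invisible(path)
}

#' Load and validate a dataset manifest
#'
#' Accepts either a CSV manifest with columns `image_path`, `mask_path`
#' (optional), `eyelid_side` (optional), `split` (optional), or a directory
#' containing `images/` and optionally `masks/` subdirectories with
#' matching file names. Every referenced file must exist; image and mask
#' shapes are checked on load; masks are binarized on read.
#'
#' @param path Manifest CSV or dataset directory.
#' @return A `dataset_manifest` data frame (image_path, mask_path,
#'   eyelid_side, split) with loaded pixel data in attributes `images` and
#'   `masks`.
#' @export
load_dataset <- function(path) {
  if (dir.exists(path)) {
    img_dir <- file.path(path, "images")
    if (!dir.exists(img_dir)) stop("no images/ directory under ", path,
                                   call. = FALSE)
    imgs <- sort(list.files(img_dir, pattern = "\\.png$", full.names = TRUE))
    if (length(imgs) == 0L) stop("no PNG images in ", img_dir, call. = FALSE)
    msk_dir <- file.path(path, "masks")
    msks <- if (dir.exists(msk_dir)) {
      file.path(msk_dir, basename(imgs))
    } else rep(NA_character_, length(imgs))
    df <- data.frame(image_path = imgs, mask_path = msks,
                     eyelid_side = NA_character_, split = NA_character_,
                     stringsAsFactors = FALSE)
  } else if (file.exists(path)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"image_path" %in% names(df)) {
      stop("manifest CSV needs an image_path column", call. = FALSE)
    }
    for (col in c("mask_path", "eyelid_side", "split")) {
      if (!col %in% names(df)) df[[col]] <- NA_character_
    }
    base <- dirname(path)
    rel <- function(p) ifelse(is.na(p) | file.exists(p), p, file.path(base, p))
    df$image_path <- rel(df$image_path)
    df$mask_path <- rel(df$mask_path)
  } else {
    stop("manifest not found: ", path, call. = FALSE)
  }
  images <- vector("list", nrow(df))
  masks <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    images[[i]] <- read_gray_png(df$image_path[i])
    if (!is.na(df$mask_path[i])) {
      masks[[i]] <- read_mask_png(df$mask_path[i])
      stop_if_shape_mismatch(images[[i]], masks[[i]],
                             paste0("image/mask pair ", basename(df$image_path[i])))
    }
  }
  attr(df, "images") <- images
  attr(df, "masks") <- masks
  class(df) <- c("dataset_manifest", "data.frame")
  df
}

#' Write a manifest back to CSV (round-trips with [load_dataset()])
#'
#' @param manifest A `dataset_manifest`.
#' @param path Output CSV.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(as.data.frame(manifest)[, c("image_path", "mask_path",
                                               "eyelid_side", "split")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Randomly split a manifest into tagged subsets
#'
#' Largest-remainder allocation of `round(n * fraction)` per tag, then a
#' seeded random assignment, so a 0.8/0.2 split of 628 records yields
#' 502/126.
#'
#' @param manifest A `dataset_manifest` (or any data frame).
#' @param fractions Named numeric vector summing to 1, e.g.
#'   `c(train = 0.8, val = 0.2)`.
#' @param seed Integer seed.
#' @return The manifest with its `split` column filled.
#' @export
split_dataset <- function(manifest, fractions = c(train = 0.8, val = 0.2),
                          seed = 1L) {
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  n <- nrow(manifest)
  raw <- n * fractions
  sizes <- floor(raw)
  left <- n - sum(sizes)
  if (left > 0) {
    ord <- order(raw - sizes, decreasing = TRUE)
    sizes[ord[seq_len(left)]] <- sizes[ord[seq_len(left)]] + 1L
  }
  tags <- rep(names(fractions), sizes)
  with_seed(seed, {
    manifest$split <- sample(tags)
  })
  manifest
}
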