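# Numbered overlay rendering: tinted gland pixels plus each gland's ordinal
# drawn above its topmost pixel, written as an RGB array.

# 3x5 bitmap font for digits 0-9, rows top to bottom.
.digit_font <- lapply(list(
  `0` = c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  `1` = c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  `2` = c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  `3` = c(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
  `4` = c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  `5` = c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  `6` = c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  `7` = c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  `8` = c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  `9` = c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1)
), function(v) matrix(v, 5, 3, byrow = TRUE))

draw_number <- function(channel, value, top, left, skip = NULL) {
  digits <- strsplit(as.character(value), "")[[1]]
  h <- nrow(channel); w <- ncol(channel)
  for (d in digits) {
    glyph <- .digit_font[[d]]
    for (r in 1:5) for (c in 1:3) {
      if (glyph[r, c] == 1) {
        y <- top + r - 1L; x <- left + c - 1L
        if (y >= 1 && y <= h && x >= 1 && x <= w &&
            (is.null(skip) || skip[y, x] == 0L)) {
          channel[y, x] <- 1
        }
      }
    }
    left <- left + 4L
  }
  channel
}

#' Render a numbered overlay of glands on a grayscale image
#'
#' Gland pixels are tinted green over the grayscale image and each gland's
#' ordinal is drawn in white above its topmost pixel. An empty gland list
#' returns the unmodified grayscale image replicated to RGB.
#'
#' @param image Grayscale matrix (0-1 or 0-255 scale).
#' @param glands List from [label_glands()].
#' @return `H x W x 3` RGB array with values in \[0, 1\]; attribute
#'   `"labels"` holds a data frame of the drawn numerals (gland, row, col).
#' @export
render_numbered_overlay <- function(image, glands) {
  if (max(image) > 1.5) image <- image / 255
  h <- nrow(image); w <- ncol(image)
  rgb <- array(rep(image, 3L), dim = c(h, w, 3L))
  labels <- data.frame(gland = integer(), row = integer(), col = integer())
  fg <- matrix(0L, h, w)  # numerals never overwrite tinted gland pixels
  for (g in glands) fg[g$pixels] <- 1L
  for (g in glands) {
    stop_if_shape_mismatch(image, matrix(0, g$mask_dim[1], g$mask_dim[2]),
                           "image and gland mask")
    idx <- cbind(g$pixels[, "row"], g$pixels[, "col"])
    # green tint: attenuate red and blue so tinted pixels (R < G) are
    # exactly the mask foreground, whatever the underlying intensity
    rgb[cbind(idx, 1L)] <- 0.55 * rgb[cbind(idx, 1L)]
    rgb[cbind(idx, 3L)] <- 0.55 * rgb[cbind(idx, 3L)]
    topmost <- g$pixels[which.min(g$pixels[, "row"]), , drop = FALSE]
    top <- max(1L, topmost[1, "row"] - 7L)
    left <- clip(topmost[1, "col"] - 1L, 1L, w)
    for (ch in 1:3) {
      rgb[, , ch] <- draw_number(rgb[, , ch], g$label, top, left, skip = fg)
    }
    labels <- rbind(labels,
                    data.frame(gland = g$label, row = top, col = left))
  }
  attr(rgb, "labels") <- labels
  rgb
}
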