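# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds, evaluates, restores. Keeps every
#' stochastic operation reproducible without clobbering the global stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' @noRd
clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @noRd
is_binary_mask <- function(m) {
  is.matrix(m) && all(m %in% c(0, 1))
}

#' @noRd
stop_if_shape_mismatch <- function(a, b, what = "inputs") {
  if (!identical(dim(a), dim(b))) {
    stop(sprintf("%s have mismatched shapes: %s vs %s", what,
                 paste(dim(a), collapse = "x"), paste(dim(b), collapse = "x")),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Bilinear / nearest resize of a numeric matrix
#'
#' Thin wrapper around EBImage::resize keeping the (row, col) orientation of
#' plain matrices. `filter = "none"` selects nearest-neighbour, which keeps
#' binary masks binary.
#' @noRd
resize_matrix <- function(x, nrow_out, ncol_out, filter = c("bilinear", "none")) {
  filter <- match.arg(filter)
  if (nrow(x) == nrow_out && ncol(x) == ncol_out) return(x)
  out <- EBImage::resize(x, w = nrow_out, h = ncol_out, filter = filter)
  matrix(as.numeric(out), nrow = nrow_out, ncol = ncol_out)
}
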