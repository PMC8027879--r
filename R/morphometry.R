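# Morphometry: from a binary gland mask to per-gland and per-eyelid
# parameters — gland number, length, width, tortuosity.
#
# Conventions: 8-connectivity for components and skeleton adjacency;
# width as inclusive pixel count X1 - X0 + 1 averaged over rows; length as
# the skeleton path length; tortuosity as skeleton path length over the
# endpoint chord. Coordinates are 1-based (row, col), rows increasing
# downward; all units are pixels at the processed resolution.

#' Label the glands of a binary mask
#'
#' Connected components of the foreground under 8-connectivity; components
#' smaller than `min_area` pixels are discarded as speckle; the surviving
#' glands are numbered 1..N left to right by centroid column (matching the
#' clinical convention of numbering glands across the eyelid).
#'
#' @param mask Binary 0/1 matrix.
#' @param min_area Minimum component area in pixels.
#' @return List of `gland_instance` objects, each with `label`, `pixels`
#'   (matrix of row/col), `row_extent`, `area` and `mask_dim`.
#' @export
label_glands <- function(mask, min_area = 10L) {
  stopifnot(is_binary_mask(mask))
  h <- nrow(mask)
  pix <- which(mask == 1L)
  if (length(pix) == 0L) return(list())
  ed <- mask_edges(mask)
  vmap <- match(ed, pix)
  dim(vmap) <- dim(ed)
  g <- igraph::make_empty_graph(n = length(pix), directed = FALSE)
  if (nrow(vmap) > 0L) g <- igraph::add_edges(g, t(vmap))
  memb <- igraph::components(g)$membership
  rows <- ((pix - 1L) %% h) + 1L
  cols <- ((pix - 1L) %/% h) + 1L
  comp_ids <- unique(memb)
  glands <- lapply(comp_ids, function(ci) {
    sel <- memb == ci
    if (sum(sel) < min_area) return(NULL)
    structure(list(label = NA_integer_,
                   pixels = cbind(row = rows[sel], col = cols[sel]),
                   row_extent = range(rows[sel]),
                   area = sum(sel),
                   mask_dim = dim(mask)),
              class = "gland_instance")
  })
  glands <- Filter(Negate(is.null), glands)
  if (length(glands) == 0L) return(list())
  ord <- order(vapply(glands, function(g) mean(g$pixels[, "col"]), 0))
  glands <- glands[ord]
  for (i in seq_along(glands)) glands[[i]]$label <- i
  glands
}

#' Mean gland width
#'
#' At each row Y within the gland's vertical extent the leftmost (X0) and
#' rightmost (X1) gland pixels are found; the width is the mean over rows
#' of the inclusive pixel count `X1 - X0 + 1`. Rows with interior gaps
#' still use the leftmost/rightmost extent.
#'
#' @param g A `gland_instance`.
#' @return Width in pixels (>= 1).
#' @export
gland_width <- function(g) {
  x0 <- tapply(g$pixels[, "col"], g$pixels[, "row"], min)
  x1 <- tapply(g$pixels[, "col"], g$pixels[, "row"], max)
  mean(x1 - x0 + 1)
}

#' Skeletonize a gland and extract its main axis
#'
#' Thins the gland's pixel set ([thin_mask()] on the cropped bounding box)
#' and returns the longest geodesic path between skeleton endpoints
#' ([skeleton_path()]) in full-image coordinates, ordered from lower to
#' higher row.
#'
#' @param g A `gland_instance`.
#' @return Integer matrix with columns `row`, `col`.
#' @export
skeletonize_gland <- function(g) {
  r0 <- min(g$pixels[, "row"]); c0 <- min(g$pixels[, "col"])
  sub <- matrix(0L, max(g$pixels[, "row"]) - r0 + 1L,
                max(g$pixels[, "col"]) - c0 + 1L)
  sub[cbind(g$pixels[, "row"] - r0 + 1L, g$pixels[, "col"] - c0 + 1L)] <- 1L
  path <- skeleton_path(thin_mask(sub))
  path[, "row"] <- path[, "row"] + r0 - 1L
  path[, "col"] <- path[, "col"] + c0 - 1L
  path
}

#' Length along an ordered 8-connected pixel path
#'
#' Sum of per-step distances: 1 for axial steps, sqrt(2) for diagonal
#' steps; 0 for a single-pixel path.
#'
#' @param path Matrix with columns `row`, `col`; consecutive rows must be
#'   8-adjacent.
#' @return Length in pixels.
#' @export
path_length <- function(path) {
  if (nrow(path) < 2L) return(0)
  dr <- diff(path[, "row"]); dc <- diff(path[, "col"])
  if (any(pmax(abs(dr), abs(dc)) != 1L)) {
    stop("path has non-adjacent consecutive pixels", call. = FALSE)
  }
  sum(sqrt(dr^2 + dc^2))
}

#' Euclidean distance between the first and last pixel of a path
#'
#' @inheritParams path_length
#' @return Chord length in pixels; 0 for a single-pixel path.
#' @export
chord_length <- function(path) {
  if (nrow(path) == 0L) stop("empty path", call. = FALSE)
  if (nrow(path) == 1L) return(0)
  sqrt(sum((path[nrow(path), ] - path[1L, ])^2))
}

#' Gland tortuosity: skeleton path length over chord length
#'
#' `tau = path_length / chord_length`; straight glands give 1. When the
#' chord degenerates below one pixel the ratio is undefined and 1 is
#' returned.
#'
#' @param g A `gland_instance`, or a skeleton path matrix.
#' @return Dimensionless tortuosity >= 1 (up to the degenerate guard).
#' @export
tortuosity <- function(g) {
  path <- if (is.matrix(g)) g else skeletonize_gland(g)
  cl <- if (nrow(path) == 0L) 0 else chord_length(path)
  if (cl < 1) return(1)
  path_length(path) / cl
}

#' Gland length
#'
#' Default (`mode = "path"`): the skeleton path length, consistent with the
#' tortuosity numerator. `mode = "extent"` instead returns the vertical
#' extent `Ymax - Ymin` of the gland pixels.
#'
#' @param g A `gland_instance`.
#' @param mode `"path"` or `"extent"`.
#' @return Length in pixels.
#' @export
gland_length <- function(g, mode = c("path", "extent")) {
  mode <- match.arg(mode)
  if (mode == "extent") return(diff(g$row_extent))
  path_length(skeletonize_gland(g))
}

#' Measure all morphometric parameters of labeled glands
#'
#' @param glands List from [label_glands()].
#' @param length_mode Passed to [gland_length()].
#' @return Data frame with one row per gland: `gland`, `area`, `width`,
#'   `length`, `tortuosity`.
#' @export
measure_glands <- function(glands, length_mode = "path") {
  if (length(glands) == 0L) {
    return(data.frame(gland = integer(), area = integer(), width = numeric(),
                      length = numeric(), tortuosity = numeric()))
  }
  do.call(rbind, lapply(glands, function(g) {
    path <- skeletonize_gland(g)
    len <- if (length_mode == "extent") diff(g$row_extent)
           else path_length(path)
    data.frame(gland = g$label, area = g$area, width = gland_width(g),
               length = len, tortuosity = tortuosity(path))
  }))
}

#' Summarize per-gland measurements into eyelid-level morphometry
#'
#' Gland count plus unweighted arithmetic means of length, width and
#' tortuosity. An empty gland list yields count 0 and `NA` means (never
#' zeros, which would corrupt averages over images).
#'
#' @param per_gland Data frame from [measure_glands()].
#' @return An `eyelid_morphometry` list.
#' @export
summarize_eyelid <- function(per_gland) {
  if (nrow(per_gland) == 0L) {
    return(structure(list(gland_count = 0L, mean_length = NA_real_,
                          mean_width = NA_real_, mean_tortuosity = NA_real_,
                          per_gland = per_gland),
                     class = "eyelid_morphometry"))
  }
  structure(list(gland_count = nrow(per_gland),
                 mean_length = mean(per_gland$length),
                 mean_width = mean(per_gland$width),
                 mean_tortuosity = mean(per_gland$tortuosity),
                 per_gland = per_gland),
            class = "eyelid_morphometry")
}

#' Full morphometric analysis of a binary gland mask
#'
#' Labels the glands, measures each, and summarizes the eyelid.
#'
#' @inheritParams label_glands
#' @inheritParams measure_glands
#' @return An `eyelid_morphometry` list (see [summarize_eyelid()]).
#' @export
analyze_mask <- function(mask, min_area = 10L, length_mode = "path") {
  summarize_eyelid(measure_glands(label_glands(mask, min_area), length_mode))
}

#' @export
print.eyelid_morphometry <- function(x, ...) {
  cat(sprintf("Eyelid morphometry: %d glands\n", x$gland_count))
  if (x$gland_count > 0L) {
    cat(sprintf("  mean length:     %.2f px\n", x$mean_length))
    cat(sprintf("  mean width:      %.2f px\n", x$mean_width))
    cat(sprintf("  mean tortuosity: %.3f\n", x$mean_tortuosity))
  }
  invisible(x)
}
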