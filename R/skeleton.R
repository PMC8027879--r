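# Topological thinning and skeleton path extraction.

#' Zhang-Suen thinning of a binary matrix to a one-pixel-wide skeleton
#'
#' Classic two-subiteration thinning: border pixels are deleted when they
#' have 2..6 foreground neighbours, exactly one 0-to-1 transition in the
#' circular neighbour sequence, and satisfy the subiteration's directional
#' conditions; iteration stops at a fixed point. Deterministic, preserves
#' connectivity, and reduces an odd-width axis-aligned bar to its exact
#' central line. Already-thin lines are fixed points.
#'
#' @param mask Binary 0/1 matrix.
#' @return Binary 0/1 matrix of the skeleton.
#' @export
thin_mask <- function(mask) {
  stopifnot(is_binary_mask(mask))
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  h <- nrow(img); w <- ncol(img)
  pad <- function(m) {
    out <- matrix(0L, h + 2L, w + 2L)
    out[2:(h + 1L), 2:(w + 1L)] <- m
    out
  }
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      p <- pad(img)
      p2 <- p[1:h, 2:(w + 1L)];        p3 <- p[1:h, 3:(w + 2L)]
      p4 <- p[2:(h + 1L), 3:(w + 2L)]; p5 <- p[3:(h + 2L), 3:(w + 2L)]
      p6 <- p[3:(h + 2L), 2:(w + 1L)]; p7 <- p[3:(h + 2L), 1:w]
      p8 <- p[2:(h + 1L), 1:w];        p9 <- p[1:h, 1:w]
      b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      seq9 <- list(p2, p3, p4, p5, p6, p7, p8, p9, p2)
      a <- matrix(0L, h, w)
      for (k in 1:8) a <- a + (seq9[[k]] == 0L & seq9[[k + 1L]] == 1L)
      cond <- if (sub == 0L) {
        (p2 * p4 * p6 == 0L) & (p4 * p6 * p8 == 0L)
      } else {
        (p2 * p4 * p8 == 0L) & (p2 * p6 * p8 == 0L)
      }
      rem <- img == 1L & b >= 2L & b <= 6L & a == 1L & cond
      if (any(rem)) {
        img[rem] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  img
}

#' 8-neighbour edge list among foreground pixels of a mask
#'
#' Returns a two-column matrix of linear pixel indices (column-major) for
#' every pair of 8-adjacent foreground pixels, each pair once.
#' @noRd
mask_edges <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- mask == 1L
  lin <- matrix(seq_len(h * w), h, w)
  edges <- list()
  shifts <- list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  for (s in shifts) {
    dy <- s[1]; dx <- s[2]
    r1 <- max(1L, 1L - dy):min(h, h - dy)
    c1 <- max(1L, 1L - dx):min(w, w - dx)
    both <- fg[r1, c1, drop = FALSE] & fg[r1 + dy, c1 + dx, drop = FALSE]
    if (any(both)) {
      a <- lin[r1, c1, drop = FALSE][both]
      b <- lin[r1 + dy, c1 + dx, drop = FALSE][both]
      edges[[length(edges) + 1L]] <- cbind(a, b)
    }
  }
  if (length(edges) == 0L) return(matrix(integer(), 0L, 2L))
  do.call(rbind, edges)
}

#' Longest geodesic path across a skeleton
#'
#' Builds the 8-connected pixel graph of the skeleton (axial edges weight 1,
#' diagonal weight sqrt(2)), finds its endpoints (degree-1 pixels) and
#' returns the maximal-length shortest path between any endpoint pair — the
#' main axis of a possibly branched skeleton. For a cycle without endpoints
#' the topmost pixel anchors the search. The returned path is ordered from
#' lower to higher row index.
#'
#' @param skeleton Binary 0/1 matrix, typically from [thin_mask()].
#' @return Integer matrix with columns `row`, `col`; one row per path
#'   pixel, consecutive rows 8-adjacent.
#' @export
skeleton_path <- function(skeleton) {
  pix <- which(skeleton == 1L)
  h <- nrow(skeleton)
  if (length(pix) == 0L) return(matrix(integer(), 0L, 2L,
                                       dimnames = list(NULL, c("row", "col"))))
  if (length(pix) == 1L) {
    return(matrix(c(((pix - 1L) %% h) + 1L, ((pix - 1L) %/% h) + 1L),
                  1L, 2L, dimnames = list(NULL, c("row", "col"))))
  }
  ed <- mask_edges(skeleton)
  vmap <- match(ed, pix)
  dim(vmap) <- dim(ed)
  rows <- ((pix - 1L) %% h) + 1L
  cols <- ((pix - 1L) %/% h) + 1L
  wts <- sqrt((rows[vmap[, 1]] - rows[vmap[, 2]])^2 +
                (cols[vmap[, 1]] - cols[vmap[, 2]])^2)
  g <- igraph::graph_from_edgelist(vmap, directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = wts)
  if (igraph::vcount(g) < length(pix)) {
    g <- igraph::add_vertices(g, length(pix) - igraph::vcount(g))
  }
  deg <- igraph::degree(g)
  ends <- which(deg == 1L)
  if (length(ends) == 0L) ends <- which.min(rows)  # cycle: anchor at top
  d <- igraph::distances(g, v = ends, to = ends)
  best <- arrayInd(which.max(d), dim(d))
  from <- ends[best[1]]; to <- ends[best[2]]
  if (from == to) {
    vp <- from
  } else {
    vp <- as.integer(igraph::shortest_paths(g, from = from, to = to,
                                            output = "vpath")$vpath[[1]])
  }
  path <- cbind(row = rows[vp], col = cols[vp])
  if (path[1L, "row"] > path[nrow(path), "row"]) {
    path <- path[rev(seq_len(nrow(path))), , drop = FALSE]
  }
  path
}
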