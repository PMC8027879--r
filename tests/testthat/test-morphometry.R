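# Morphometry: labeling, width, skeleton, path/chord lengths, tortuosity,
# eyelid summaries, overlay rendering.

three_bar_mask <- function() {
  m <- matrix(0L, 40, 60)
  m[5:35, 10:14] <- 1L
  m[8:30, 25:27] <- 1L
  m[10:38, 45:50] <- 1L
  m
}

test_that("gland labeling matches a flood-fill oracle and numbers left to right", {
  m <- three_bar_mask()
  glands <- label_glands(m)
  expect_length(glands, 3L)
  expect_identical(vapply(glands, `[[`, 0L, "label"), 1:3)
  cols <- vapply(glands, function(g) mean(g$pixels[, "col"]), 0)
  expect_true(all(diff(cols) > 0))

  expect_identical(label_glands(matrix(0L, 10, 10)), list())

  set.seed(7)
  for (rep in 1:20) {
    rm <- matrix(rbinom(24 * 24, 1, 0.4), 24, 24)
    expect_equal(length(label_glands(rm, min_area = 1L)),
                 oracle_component_count(rm))
  }

  # speckle below min_area is discarded
  sp <- matrix(0L, 20, 20)
  sp[5:15, 3:7] <- 1L
  sp[2, 15] <- 1L
  expect_length(label_glands(sp, min_area = 10L), 1L)
})

test_that("width is the row-wise inclusive extent, averaged", {
  m <- matrix(0L, 30, 30); m[5:25, 10:19] <- 1L
  expect_equal(gland_width(label_glands(m)[[1]]), 10)

  thin <- matrix(0L, 30, 30); thin[5:25, 12] <- 1L
  expect_equal(gland_width(label_glands(thin, min_area = 5L)[[1]]), 1)

  # staircase with per-row extents 3, 5, 7 -> mean 5, vs direct scan
  st <- matrix(0L, 10, 20)
  st[4, 8:10] <- 1L; st[5, 7:11] <- 1L; st[6, 6:12] <- 1L
  g <- label_glands(st, min_area = 1L)[[1]]
  expect_equal(gland_width(g), 5)
  scan <- mean(sapply(4:6, function(y) diff(range(which(st[y, ] == 1L))) + 1))
  expect_equal(gland_width(g), scan)

  # rows with interior gaps still use leftmost/rightmost extent
  gap <- matrix(0L, 10, 20)
  gap[4:6, 5:6] <- 1L; gap[4:6, 8:9] <- 1L; gap[4, 7] <- 1L
  gg <- label_glands(gap, min_area = 1L)
  expect_length(gg, 1L)
  expect_equal(gland_width(gg[[1]]), 5)
})

test_that("skeletonization thins to the exact axis of symmetric bars", {
  m <- matrix(0L, 80, 50); m[10:59, 16:24] <- 1L
  g <- label_glands(m)[[1]]
  path <- skeletonize_gland(g)
  expect_identical(unique(path[, "col"]), 20L)      # central column
  expect_identical(diff(path[, "row"]), rep(1L, nrow(path) - 1L))
  expect_equal(tortuosity(path), 1)

  # already-thin input is a fixed point
  line <- matrix(0L, 20, 20); line[3:17, 10] <- 1L
  expect_identical(thin_mask(line), line)
  lp <- skeleton_path(line)
  expect_equal(nrow(lp), 15L)

  # branched skeleton: path is the longest endpoint-to-endpoint geodesic
  y <- matrix(0L, 30, 30)
  y[15:28, 15] <- 1L                                 # trunk
  for (k in 0:10) { y[14 - k, 15 - k] <- 1L }        # long arm
  for (k in 0:4) { y[14 - k, 15 + k] <- 1L }         # short arm
  p <- skeleton_path(y)
  expect_equal(path_length(p), oracle_longest_geodesic(y), tolerance = 1e-9)
  expect_equal(path_length(p), 14 + 10 * sqrt(2))    # trunk + long arm
})

test_that("path and chord lengths follow the step metric", {
  ax <- cbind(row = 0:2 + 1L, col = rep(1L, 3))
  expect_equal(path_length(ax), 2)
  di <- cbind(row = 1:3, col = 1:3)
  expect_equal(path_length(di), 2 * sqrt(2))
  expect_equal(path_length(di[1, , drop = FALSE]), 0)
  expect_error(path_length(cbind(row = c(1L, 5L), col = c(1L, 1L))),
               "adjacent")

  set.seed(11)
  pos <- c(50L, 50L); walk <- matrix(pos, 1)
  for (i in 1:50) {
    step <- c(sample(-1:1, 1), sample(-1:1, 1))
    if (all(step == 0L)) step <- c(1L, 0L)
    pos <- pos + step
    walk <- rbind(walk, pos)
  }
  colnames(walk) <- c("row", "col")
  euclid <- sum(sqrt(rowSums(diff(walk)^2)))
  expect_equal(path_length(walk), euclid, tolerance = 1e-12)

  expect_equal(chord_length(cbind(row = rep(1L, 11), col = 0:10 + 1L)), 10)
  expect_equal(chord_length(cbind(row = c(1L, 4L), col = c(1L, 5L))), 5)
  loop <- cbind(row = c(1L, 1L, 2L, 2L, 1L), col = c(1L, 2L, 2L, 1L, 1L))
  expect_equal(chord_length(loop), 0)
  expect_equal(tortuosity(loop), 1)  # degenerate chord guard
  expect_error(chord_length(matrix(integer(), 0, 2)), "empty")
})

test_that("tortuosity is 1 for straight glands and pi/2 for semicircular bands", {
  m <- matrix(0L, 80, 50); m[10:59, 16:24] <- 1L
  expect_equal(tortuosity(label_glands(m)[[1]]), 1)

  for (r in c(40L, 60L)) {
    band <- semicircle_band_mask(r, 3L)
    g <- label_glands(band)[[1]]
    tau <- tortuosity(g)
    expect_lt(abs(tau - pi / 2) / (pi / 2), 0.03)
  }
})

test_that("morphometrics are translation invariant and tortuosity >= 1", {
  s <- simulate_phantom(phantom_config_small(4L, clean = TRUE))
  base <- analyze_mask(s$mask)
  sh <- matrix(0L, 70, 70)          # same mask translated by (+2, +2)
  sh[3:66, 3:66] <- s$mask
  shifted <- analyze_mask(sh)
  expect_equal(shifted$gland_count, base$gland_count)
  expect_equal(shifted$mean_width, base$mean_width)
  expect_equal(shifted$mean_length, base$mean_length)
  expect_equal(shifted$mean_tortuosity, base$mean_tortuosity)
  expect_true(all(base$per_gland$tortuosity >= 1))
})

test_that("eyelid summaries average glands and mark empties as undefined", {
  m <- three_bar_mask()
  res <- analyze_mask(m, min_area = 5L)
  expect_identical(res$gland_count, 3L)
  expect_equal(res$mean_width, mean(res$per_gland$width))
  expect_equal(res$mean_width, mean(c(5, 3, 6)))

  single <- analyze_mask(matrix(c(rep(0L, 40), rep(1L, 60), rep(0L, 100)),
                                20, 10), min_area = 5L)
  expect_identical(single$gland_count, 1L)
  expect_equal(single$mean_length, single$per_gland$length[1])

  empty <- analyze_mask(matrix(0L, 20, 20))
  expect_identical(empty$gland_count, 0L)
  expect_true(is.na(empty$mean_length) && is.na(empty$mean_width) &&
                is.na(empty$mean_tortuosity))
})

test_that("numbered overlays tint exactly the mask pixels and draw one numeral per gland", {
  m <- three_bar_mask()
  img <- matrix(0.3, 40, 60)
  glands <- label_glands(m)
  ov <- render_numbered_overlay(img, glands)
  expect_equal(dim(ov), c(40L, 60L, 3L))
  tinted <- ov[, , 1] < ov[, , 2]
  expect_identical((tinted) + 0L, m)
  expect_equal(nrow(attr(ov, "labels")), 3L)

  ov0 <- render_numbered_overlay(img, list())
  expect_equal(ov0[, , 1], img, ignore_attr = TRUE)
  expect_identical(ov0[, , 1], ov0[, , 2])
})
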