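#' Configuration for the synthetic meibography phantom generator
#'
#' Phantoms emulate infrared meibography of the everted eyelid: a set of
#' bright, vertically oriented, possibly curved gland strips on a darker
#' tarsal background, degraded by the acquisition artifacts that make real
#' meibography hard (defocus blur, specular reflections, non-uniform
#' illumination, sensor noise). Every phantom carries its exact ground-truth
#' mask and analytically known morphometry, so the segmentation and
#' morphometry code can be validated against values that do not depend on
#' any rendered image.
#'
#' Gland centerlines are sinusoids
#' \eqn{x(y) = a + A \sin(2\pi (y - y_0)/\lambda + \phi)}, which gives a
#' closed-form arc length (hence tortuosity) by quadrature. Upper-eyelid
#' glands are longer than lower-eyelid glands, matching clinical morphology.
#'
#' @param image_height,image_width Canvas size in pixels. The default 256 is
#'   the working resolution of the segmentation pipeline.
#' @param gland_count Number of glands per phantom.
#' @param eyelid_side `"upper"` or `"lower"`; only changes the default gland
#'   length range (upper glands run longer).
#' @param length_range Vertical gland extent range in pixels; `NULL` picks a
#'   side-dependent default scaled to the canvas height.
#' @param half_width_range Integer range of gland half-widths in pixels; a
#'   gland strip is `2 * half_width + 1` pixels wide at integer centers.
#' @param amplitude_range Lateral sinusoidal displacement range, pixels.
#' @param wavelength_range Sinusoid wavelength range, pixels.
#' @param min_gap Minimum horizontal background gap between neighbouring
#'   strips at every shared row, pixels.
#' @param gland_intensity,background_intensity Noise-free 8-bit intensities
#'   of gland and background pixels (glands appear bright in IR meibography).
#' @param blur_sigma Gaussian defocus blur sigma in pixels (0 disables).
#' @param specular_spot_count Number of saturated specular discs (0 disables).
#' @param illumination_gradient_strength Relative amplitude of a horizontal
#'   linear illumination ramp (0 disables; 0.25 means +/-12.5\% across the
#'   image).
#' @param noise_sigma Additive Gaussian noise sigma on the 0-255 scale.
#' @param margin Border in pixels kept free of gland pixels.
#' @param seed Integer seed; identical seed implies identical phantoms.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_height = 256L, image_width = 256L,
                           gland_count = 12L,
                           eyelid_side = c("upper", "lower"),
                           length_range = NULL,
                           half_width_range = c(2L, 3L),
                           amplitude_range = c(1, 3),
                           wavelength_range = c(90, 140),
                           min_gap = 2L,
                           gland_intensity = 200,
                           background_intensity = 50,
                           blur_sigma = 1,
                           specular_spot_count = 2L,
                           illumination_gradient_strength = 0.25,
                           noise_sigma = 8,
                           margin = 6L,
                           seed = 1L) {
  eyelid_side <- match.arg(eyelid_side)
  if (is.null(length_range)) {
    scale <- image_height / 256
    length_range <- if (eyelid_side == "upper") c(160, 220) * scale
                    else c(100, 140) * scale
    length_range <- round(length_range)
  }
  cfg <- list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    gland_count = as.integer(gland_count),
    eyelid_side = eyelid_side,
    length_range = as.numeric(length_range),
    half_width_range = as.integer(half_width_range),
    amplitude_range = as.numeric(amplitude_range),
    wavelength_range = as.numeric(wavelength_range),
    min_gap = as.integer(min_gap),
    gland_intensity = gland_intensity,
    background_intensity = background_intensity,
    blur_sigma = blur_sigma,
    specular_spot_count = as.integer(specular_spot_count),
    illumination_gradient_strength = illumination_gradient_strength,
    noise_sigma = noise_sigma,
    margin = as.integer(margin),
    seed = as.integer(seed)
  )
  stopifnot(cfg$gland_count >= 0, cfg$image_height > 0, cfg$image_width > 0,
            diff(cfg$length_range) >= 0, diff(cfg$half_width_range) >= 0,
            cfg$half_width_range[1] >= 1,
            diff(cfg$amplitude_range) >= 0, cfg$amplitude_range[1] >= 0,
            cfg$wavelength_range[1] > 0, cfg$min_gap >= 0)
  if (cfg$length_range[2] + 2 * cfg$margin > cfg$image_height) {
    stop("length_range does not fit the canvas height with the given margin",
         call. = FALSE)
  }
  class(cfg) <- "phantom_config"
  cfg
}

#' One synthetic gland: a sinusoidal strip specification
#'
#' The centerline is `x(y) = anchor_column + amplitude *
#' sin(2*pi*(y - top_row)/wavelength + phase)` for rows `top_row..bottom_row`;
#' the strip covers every integer column within `half_width` of the
#' centerline. Coordinates are 1-based (row, col), rows increasing downward.
#'
#' @param anchor_column,top_row,bottom_row,half_width,amplitude,wavelength,phase
#'   Geometric parameters; see Details.
#' @return A `gland_spec` list.
#' @export
gland_spec <- function(anchor_column, top_row, bottom_row, half_width,
                       amplitude = 0, wavelength = 100, phase = 0) {
  stopifnot(bottom_row > top_row, half_width >= 1, amplitude >= 0,
            wavelength > 0)
  structure(list(anchor_column = anchor_column,
                 top_row = as.integer(top_row),
                 bottom_row = as.integer(bottom_row),
                 half_width = as.integer(half_width),
                 amplitude = amplitude, wavelength = wavelength,
                 phase = phase),
            class = "gland_spec")
}

#' Centerline column of a gland spec at given rows
#' @noRd
spec_centerline <- function(spec, rows) {
  spec$anchor_column +
    spec$amplitude * sin(2 * pi * (rows - spec$top_row) / spec$wavelength +
                           spec$phase)
}

#' Sample non-overlapping gland specifications
#'
#' Draws `gland_count` gland strips whose maximal lateral extents
#' (`half_width + amplitude`) are separated by at least `min_gap` background
#' columns at every row, by partitioning the image width into randomly
#' jittered slots. Deterministic given `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return List of [gland_spec()] objects ordered left to right.
#' @export
sample_gland_specs <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n <- config$gland_count
  if (n == 0L) return(list())
  with_seed(config$seed, {
    hwr <- config$half_width_range
    hw <- hwr[1] + sample.int(hwr[2] - hwr[1] + 1L, n, replace = TRUE) - 1L
    amp <- stats::runif(n, config$amplitude_range[1], config$amplitude_range[2])
    wl <- stats::runif(n, config$wavelength_range[1], config$wavelength_range[2])
    phase <- stats::runif(n, 0, 2 * pi)
    len <- round(stats::runif(n, config$length_range[1], config$length_range[2]))
    top <- config$margin +
      floor(stats::runif(n) * pmax(1, config$image_height - 2 * config$margin - len))
    ext <- hw + ceiling(amp)              # max lateral reach from anchor
    slot <- 2L * ext + 1L                 # columns a gland can ever occupy
    need <- sum(slot) + (n - 1L) * config$min_gap + 2L * config$margin
    if (need > config$image_width) {
      stop(sprintf(paste0(
        "cannot pack %d glands: maximal strip extents plus gaps need %d ",
        "columns but the image has %d (reduce gland_count, half_width_range ",
        "or amplitude_range)"), n, need, config$image_width), call. = FALSE)
    }
    slack <- config$image_width - need
    u <- stats::runif(n + 1L)
    extra <- diff(floor(cumsum(c(0, u / sum(u))) * slack))  # integer split
    lefts <- config$margin + cumsum(c(0L, slot[-n] + config$min_gap)) +
      cumsum(extra[-(n + 1L)])
    anchors <- lefts + ext + 1L           # 1-based anchor columns
    lapply(seq_len(n), function(i) {
      gland_spec(anchor_column = anchors[i], top_row = top[i],
                 bottom_row = top[i] + len[i], half_width = hw[i],
                 amplitude = amp[i], wavelength = wl[i], phase = phase[i])
    })
  })
}

#' Per-row foreground column interval of a spec
#'
#' The strip is centered on the pixel column nearest the continuous
#' centerline, so every row is exactly `2 * half_width + 1` pixels wide and
#' the rendered width matches the analytic width.
#' @noRd
spec_row_interval <- function(spec, rows) {
  ctr <- round(spec_centerline(spec, rows))
  cbind(lo = ctr - spec$half_width, hi = ctr + spec$half_width)
}

#' Render the exact binary ground-truth mask of a set of gland specs
#'
#' Pixel `(y, x)` is foreground iff `|x - round(centerline(y))| <=
#' half_width` for some spec whose row range contains `y`: each row of a
#' strip is the `2 * half_width + 1` pixel columns centered on the pixel
#' nearest the continuous centerline. White-on-black convention: 1 = gland.
#' Errors if two specs touch (the merged components would corrupt gland
#' counting).
#'
#' @param specs List of [gland_spec()].
#' @param shape `c(height, width)` in pixels.
#' @return Integer matrix of 0/1 with `length(specs)` connected components.
#' @export
render_gland_mask <- function(specs, shape) {
  h <- shape[1]; w <- shape[2]
  mask <- matrix(0L, h, w)
  occ <- vector("list", h)  # per-row intervals for the overlap check
  for (s in specs) {
    rows <- s$top_row:s$bottom_row
    if (s$top_row < 1 || s$bottom_row > h) {
      stop("gland spec exceeds image rows", call. = FALSE)
    }
    iv <- spec_row_interval(s, rows)
    if (any(iv[, "lo"] < 1) || any(iv[, "hi"] > w)) {
      stop("gland spec centerline +/- half_width exceeds image columns",
           call. = FALSE)
    }
    for (k in seq_along(rows)) {
      y <- rows[k]
      for (prev in occ[[y]]) {
        if (iv[k, "lo"] <= prev[2] + 1L && iv[k, "hi"] >= prev[1] - 1L) {
          stop("overlapping gland specs: rendered mask would merge glands",
               call. = FALSE)
        }
      }
      occ[[y]] <- c(occ[[y]], list(c(iv[k, "lo"], iv[k, "hi"])))
      mask[y, iv[k, "lo"]:iv[k, "hi"]] <- 1L
    }
  }
  mask
}

#' Gaussian blur with a normalized kernel (EBImage backend)
#' @noRd
blur_matrix <- function(x, sigma) {
  if (sigma <= 0) return(x)
  out <- EBImage::gblur(x, sigma = sigma)
  matrix(as.numeric(out), nrow = nrow(x), ncol = ncol(x))
}

#' Render a grayscale phantom image from a mask
#'
#' Applies the artifact chain in fixed order: illumination gradient, then
#' gland/background intensity assignment, Gaussian defocus blur, saturated
#' specular discs, additive Gaussian noise; finally clips to the 8-bit range
#' 0-255. With every artifact strength at zero the output is the exact
#' two-valued image \{background_intensity, gland_intensity\}.
#'
#' @param mask Binary gland mask.
#' @param config A [phantom_config()].
#' @param seed Seed for the stochastic artifacts (specular placement, noise);
#'   defaults to `config$seed + 1`.
#' @return Numeric matrix with values in \[0, 255\].
#' @export
render_phantom_image <- function(mask, config, seed = config$seed + 1L) {
  stopifnot(is_binary_mask(mask))
  h <- nrow(mask); w <- ncol(mask)
  img <- config$background_intensity +
    (config$gland_intensity - config$background_intensity) * mask
  if (config$illumination_gradient_strength > 0) {
    ramp <- 1 + config$illumination_gradient_strength *
      (matrix(rep(seq_len(w), each = h), h, w) - (w + 1) / 2) / w
    img <- img * ramp
  }
  img <- blur_matrix(img, config$blur_sigma)
  with_seed(seed, {
    if (config$specular_spot_count > 0) {
      cy <- stats::runif(config$specular_spot_count, 1, h)
      cx <- stats::runif(config$specular_spot_count, 1, w)
      r <- stats::runif(config$specular_spot_count, 2, 5)
      rows <- matrix(rep(seq_len(h), w), h, w)
      cols <- matrix(rep(seq_len(w), each = h), h, w)
      for (i in seq_len(config$specular_spot_count)) {
        img[(rows - cy[i])^2 + (cols - cx[i])^2 <= r[i]^2] <- 255
      }
    }
    if (config$noise_sigma > 0) {
      img <- img + stats::rnorm(h * w, 0, config$noise_sigma)
    }
  })
  clip(img, 0, 255)
}

#' Analytic morphometry expected from gland specifications
#'
#' Computes, per gland and without ever touching a rendered mask: length as
#' the centerline arc length over the gland's row range (adaptive
#' quadrature), width as `2 * half_width + 1` (inclusive pixel count),
#' tortuosity as arc length over the Euclidean distance between the
#' centerline endpoints. Straight glands have tortuosity exactly 1.
#'
#' @param specs List of [gland_spec()].
#' @return An `eyelid_morphometry` list: `gland_count`, `mean_length`,
#'   `mean_width`, `mean_tortuosity`, and a `per_gland` data frame.
#' @export
expected_morphometry <- function(specs) {
  n <- length(specs)
  if (n == 0L) {
    return(structure(list(gland_count = 0L, mean_length = NA_real_,
                          mean_width = NA_real_, mean_tortuosity = NA_real_,
                          per_gland = data.frame()),
                     class = "eyelid_morphometry"))
  }
  per <- do.call(rbind, lapply(seq_len(n), function(i) {
    s <- specs[[i]]
    omega <- 2 * pi / s$wavelength
    dxdy <- function(y) s$amplitude * omega *
      cos(omega * (y - s$top_row) + s$phase)
    arc <- stats::integrate(function(y) sqrt(1 + dxdy(y)^2),
                            s$top_row, s$bottom_row,
                            rel.tol = 1e-8, subdivisions = 400L)$value
    ends <- spec_centerline(s, c(s$top_row, s$bottom_row))
    chord <- sqrt((s$bottom_row - s$top_row)^2 + diff(ends)^2)
    data.frame(gland = i, length = arc, width = 2 * s$half_width + 1,
               tortuosity = if (s$amplitude == 0) 1 else arc / chord)
  }))
  structure(list(gland_count = n,
                 mean_length = mean(per$length),
                 mean_width = mean(per$width),
                 mean_tortuosity = mean(per$tortuosity),
                 per_gland = per),
            class = "eyelid_morphometry")
}

#' Generate one phantom sample (image + mask + specs + analytic morphometry)
#'
#' @param config A [phantom_config()]; `config$seed` fully determines the
#'   output.
#' @return A `phantom_sample` list with elements `image` (0-255 grayscale
#'   matrix), `mask` (0/1 matrix), `specs`, `expected`
#'   (an `eyelid_morphometry`), and the `config` used.
#' @export
simulate_phantom <- function(config) {
  specs <- sample_gland_specs(config)
  mask <- render_gland_mask(specs,
                            c(config$image_height, config$image_width))
  img <- render_phantom_image(mask, config)
  structure(list(image = img, mask = mask, specs = specs,
                 expected = expected_morphometry(specs), config = config),
            class = "phantom_sample")
}

#' Generate a batch of phantoms, optionally writing them to disk
#'
#' Sample `i` uses seed `seed + i - 1`. When `out_dir` is given, each sample
#' is written as 8-bit grayscale PNGs (`phantom_###.png`,
#' `phantom_###_mask.png`) plus a JSON sidecar with the gland specs and the
#' analytic morphometry.
#'
#' @param config A [phantom_config()] template.
#' @param n Number of phantoms.
#' @param seed Base seed; defaults to `config$seed`.
#' @param out_dir Optional output directory.
#' @return Invisible list of `phantom_sample` objects.
#' @export
simulate_phantoms <- function(config, n, seed = config$seed, out_dir = NULL) {
  samples <- lapply(seq_len(n), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + i - 1L)
    simulate_phantom(cfg)
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      id <- sprintf("phantom_%03d", i)
      write_gray_png(samples[[i]]$image / 255,
                     file.path(out_dir, paste0(id, ".png")))
      write_gray_png(samples[[i]]$mask,
                     file.path(out_dir, paste0(id, "_mask.png")))
      side <- lapply(samples[[i]]$specs, unclass)
      exp <- samples[[i]]$expected
      jsonlite::write_json(
        list(specs = side,
             expected = list(gland_count = exp$gland_count,
                             mean_length = exp$mean_length,
                             mean_width = exp$mean_width,
                             mean_tortuosity = exp$mean_tortuosity)),
        file.path(out_dir, paste0(id, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  }
  invisible(samples)
}
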