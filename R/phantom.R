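# Seeded generator of synthetic CT-like slice/mask pairs. The phantoms carry
# the statistical structure the segmentation task assumes: one or two
# kidney-shaped (rotated elliptical) bright regions on a darker background,
# additive Gaussian noise, and - the hard case - hollow interiors emulating
# the renal collecting system, which looks like background and is excluded
# from the kidney label.

#' Phantom generator configuration
#'
#' @param image_size pixels per side (square); must be at least 32 and
#'   divisible by 8 (the generator down-samples three times).
#' @param n_regions_choices allowed counts of kidney-like regions per slice,
#'   a subset of `0:2`. With two regions the centres are constrained to the
#'   left and right image halves, mimicking left/right kidneys.
#' @param region_axis_range min/max ellipse semi-axes in pixels.
#' @param hollow_prob probability that a region contains an excluded hollow
#'   interior (collecting-system analogue).
#' @param hollow_scale hollow semi-axes as a fraction of the region semi-axes.
#' @param fg_intensity,bg_intensity mean gray levels in \[0, 1\].
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param seed RNG seed; each pair draws from an independent stream derived
#'   from `(seed, index)` so datasets are order-independent.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(image_size = 64L,
                           n_regions_choices = c(1L, 2L),
                           region_axis_range = c(8, 16),
                           hollow_prob = 0.5,
                           hollow_scale = 0.4,
                           fg_intensity = 0.65,
                           bg_intensity = 0.25,
                           noise_sd = 0.08,
                           seed = 1L) {
  if (image_size < 32L || image_size %% 8L != 0L) {
    abort("image_size must be >= 32 and divisible by 8")
  }
  if (!all(n_regions_choices %in% 0:2) || length(n_regions_choices) < 1) {
    abort("n_regions_choices must be a non-empty subset of 0:2")
  }
  if (hollow_prob < 0 || hollow_prob > 1) abort("hollow_prob must be in [0, 1]")
  if (hollow_scale <= 0 || hollow_scale >= 1) abort("hollow_scale must be in (0, 1)")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (diff(region_axis_range) < 0 || region_axis_range[1] <= 1) {
    abort("region_axis_range must be increasing with minimum > 1")
  }
  if (2 * region_axis_range[2] + 2 > image_size) {
    abort("region_axis_range exceeds image bounds: largest ellipse cannot fit")
  }
  structure(list(image_size = as.integer(image_size),
                 n_regions_choices = sort(as.integer(unique(n_regions_choices))),
                 region_axis_range = as.numeric(region_axis_range),
                 hollow_prob = hollow_prob, hollow_scale = hollow_scale,
                 fg_intensity = fg_intensity, bg_intensity = bg_intensity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_config")
}

# run code under a private RNG stream derived from (seed, index), restoring
# the caller's RNG state afterwards
with_pair_seed <- function(seed, index, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) * 100003 + as.numeric(index)) %% 2147483647)
  force(code)
}

# pixel-centre ellipse membership on an n x n grid
ellipse_mask <- function(n, cx, cy, a, b, theta) {
  xs <- matrix(rep(seq_len(n), each = n), n)      # column index
  ys <- matrix(rep(seq_len(n), times = n), n)     # row index
  dx <- xs - cx; dy <- ys - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u * u + v * v <= 1
}

#' Generate one phantom slice/mask pair
#'
#' Deterministic in `(config$seed, index)`: the same call always returns a
#' bit-identical pair regardless of what was generated before.
#'
#' @param config a [phantom_config()].
#' @param index non-negative integer identifying the pair within a dataset.
#' @return a `phantom_pair`: list with `image` (matrix in \[0, 1\]), `mask`
#'   (binary integer matrix; hollow interiors are 0), and `meta` (tibble row
#'   with region count, hollow flags, seed used).
#' @export
generate_pair <- function(config, index = 0L) {
  stopifnot(inherits(config, "phantom_config"), index >= 0)
  n <- config$image_size
  with_pair_seed(config$seed, index, {
    k <- if (length(config$n_regions_choices) == 1L) {
      config$n_regions_choices
    } else {
      sample(config$n_regions_choices, 1L)
    }
    mask <- matrix(FALSE, n, n)
    hollow <- matrix(FALSE, n, n)
    hollow_flags <- logical(0)
    if (k > 0) {
      hollow_flags <- logical(k)
      for (r in seq_len(k)) {
        a <- runif(1, config$region_axis_range[1], config$region_axis_range[2])
        b <- runif(1, config$region_axis_range[1], config$region_axis_range[2])
        theta <- runif(1, 0, pi)
        m <- ceiling(max(a, b)) + 1
        if (k == 2) {
          # left/right halves, like the two kidneys on an axial slice
          lo <- if (r == 1) m + 1 else n / 2 + 1
          hi <- if (r == 1) n / 2 else n - m
          cx <- runif(1, lo, max(lo, hi))
        } else {
          cx <- runif(1, m + 1, n - m)
        }
        cy <- runif(1, m + 1, n - m)
        region <- ellipse_mask(n, cx, cy, a, b, theta)
        hole <- matrix(FALSE, n, n)
        if (runif(1) < config$hollow_prob) {
          hollow_flags[r] <- TRUE
          hole <- ellipse_mask(n, cx, cy, a * config$hollow_scale,
                               b * config$hollow_scale, theta)
        }
        mask <- mask | (region & !hole)
        hollow <- hollow | hole
      }
    }
    img <- matrix(config$bg_intensity, n, n)
    img[mask] <- config$fg_intensity
    img[hollow] <- config$bg_intensity
    if (config$noise_sd > 0) {
      img <- img + matrix(rnorm(n * n, sd = config$noise_sd), n, n)
    }
    img <- pmin(pmax(img, 0), 1)
    structure(list(
      image = img,
      mask = matrix(as.integer(mask), n, n),
      meta = tibble(index = as.integer(index), n_regions = as.integer(k),
                    n_hollow = sum(hollow_flags),
                    seed = config$seed)),
      class = "phantom_pair")
  })
}

#' Generate a phantom dataset
#'
#' Pair `i` equals `generate_pair(config, i - 1)`, so datasets are
#' order-independent and reproducible pair-by-pair.
#'
#' @param config a [phantom_config()].
#' @param n number of pairs, >= 1.
#' @return a `phantom_dataset`: list with `pairs` (list of `phantom_pair`)
#'   and `manifest` (one tibble row per pair plus the config as attribute).
#' @export
generate_dataset <- function(config, n) {
  stopifnot(inherits(config, "phantom_config"), n >= 1)
  pairs <- purrr::map(seq_len(n) - 1L, function(i) generate_pair(config, i))
  manifest <- purrr::list_rbind(purrr::map(pairs, "meta"))
  manifest$fg_fraction <- purrr::map_dbl(pairs, function(p) mean(p$mask))
  structure(list(pairs = pairs, manifest = manifest, config = config),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset> %d pairs, %dx%d px, seed %d\n",
              length(x$pairs), x$config$image_size, x$config$image_size,
              x$config$seed))
  print(x$manifest, n = 5)
  invisible(x)
}

#' Write a phantom dataset as PNG pairs plus a JSON manifest
#'
#' Images are written as 8-bit grayscale PNGs, masks as \{0, 255\} PNGs,
#' plus `manifest.json` holding the config and per-pair metadata.
#'
#' @param dataset a `phantom_dataset`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in dataset$pairs) {
    i <- p$meta$index
    png::writePNG(p$image, file.path(dir, sprintf("img_%04d.png", i)))
    png::writePNG(p$mask + 0, file.path(dir, sprintf("mask_%04d.png", i)))
  }
  manifest <- list(
    config = unclass(dataset$config),
    pairs = dataset$manifest)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a phantom dataset written by [write_phantom_dataset()]
#'
#' @param dir dataset directory.
#' @return a `phantom_dataset`. PNG round-tripping quantises images to 8 bits;
#'   masks round-trip exactly.
#' @export
read_phantom_dataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  cfg <- do.call(phantom_config, mf$config[setdiff(names(mf$config), NULL)])
  rows <- as_tibble(mf$pairs)
  pairs <- purrr::map(seq_len(nrow(rows)), function(j) {
    i <- rows$index[j]
    img <- png::readPNG(file.path(dir, sprintf("img_%04d.png", i)))
    msk <- png::readPNG(file.path(dir, sprintf("mask_%04d.png", i)))
    structure(list(image = img,
                   mask = matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk)),
                   meta = rows[j, ]),
              class = "phantom_pair")
  })
  structure(list(pairs = pairs, manifest = rows, config = cfg),
            class = "phantom_dataset")
}

#' Plot a phantom pair
#'
#' @param pair a `phantom_pair`.
#' @param ... unused.
#' @return a ggplot showing the image with the mask boundary region overlaid.
#' @export
autoplot.phantom_pair <- function(pair, ...) {
  df <- tidyr::expand_grid(col = seq_len(ncol(pair$image)),
                           row = seq_len(nrow(pair$image)))
  df$intensity <- as.numeric(pair$image)
  df$mask <- as.numeric(pair$mask)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$mask), breaks = 0.5,
                          colour = "red", linewidth = 0.3) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "intensity")
}
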