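#' Specification for a synthetic H&E-like gland tile
#'
#' Describes one deterministic synthetic histology tile: ring-shaped glands
#' (an epithelial border around a pale lumen) scattered on a stroma
#' background, mimicking the content of H&E-stained colorectal sections at
#' whole-slide patch scale. The same spec always renders the same tile.
#'
#' @param seed Integer seed controlling gland placement and noise.
#' @param width,height Tile dimensions in pixels (at least 112).
#' @param n_glands Number of glands to attempt to place.
#' @param radius_range Length-2 numeric, min/max gland semi-major axis in
#'   pixels (min at least 4).
#' @param lumen_ratio Fraction of the gland radius occupied by the lumen,
#'   strictly between 0 and 1.
#' @param axis_ratio Length-2 numeric range for the minor/major axis ratio
#'   of the gland ellipses (1 = circles).
#' @param noise_sigma Per-channel Gaussian intensity noise standard
#'   deviation on the 0-255 scale; 0 gives a noiseless tile whose three
#'   tissue classes are exactly the palette colors (and hence linearly
#'   separable in RGB).
#' @param palette List with elements `stroma`, `epithelium`, `lumen`, each
#'   an RGB triplet on the 0-255 scale.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L,
                           width = 775L, height = 522L,
                           n_glands = 6L,
                           radius_range = c(30, 60),
                           lumen_ratio = 0.5,
                           axis_ratio = c(0.6, 1),
                           noise_sigma = 0,
                           palette = list(stroma = c(231, 180, 188),
                                          epithelium = c(121, 77, 153),
                                          lumen = c(244, 240, 239))) {
  spec <- list(seed = as.integer(seed), width = as.integer(width),
               height = as.integer(height), n_glands = as.integer(n_glands),
               radius_range = as.numeric(radius_range),
               lumen_ratio = lumen_ratio,
               axis_ratio = as.numeric(axis_ratio),
               noise_sigma = noise_sigma,
               palette = lapply(palette, as.numeric))
  class(spec) <- "synthetic_spec"
  validate_synthetic_spec(spec)
  spec
}

validate_synthetic_spec <- function(spec) {
  if (spec$width < 112L || spec$height < 112L) {
    stop_maaseg("tile dimensions must be at least 112x112, got ",
                spec$width, "x", spec$height, class = "maaseg_config_error")
  }
  if (spec$lumen_ratio <= 0 || spec$lumen_ratio >= 1) {
    stop_maaseg("lumen_ratio must lie strictly in (0, 1)",
                class = "maaseg_config_error")
  }
  if (length(spec$radius_range) != 2L || spec$radius_range[1L] < 4) {
    stop_maaseg("radius_range must be (min, max) with min >= 4",
                class = "maaseg_config_error")
  }
  if (length(spec$axis_ratio) != 2L || spec$axis_ratio[1L] <= 0 ||
      spec$axis_ratio[2L] > 1) {
    stop_maaseg("axis_ratio must be a range within (0, 1]",
                class = "maaseg_config_error")
  }
  if (!all(c("stroma", "epithelium", "lumen") %in% names(spec$palette))) {
    stop_maaseg("palette must name stroma, epithelium and lumen colors",
                class = "maaseg_config_error")
  }
  invisible(spec)
}

# Evaluate an ellipse membership test over a bounding box; returns linear
# pixel indices (column-major, y fastest) inside the ellipse.
ellipse_pixels <- function(cx, cy, a, b, theta, width, height) {
  r <- ceiling(max(a, b))
  xs <- max(1, floor(cx - r)):min(width, ceiling(cx + r))
  ys <- max(1, floor(cy - r)):min(height, ceiling(cy + r))
  dx <- rep(xs - cx, each = length(ys))
  dy <- rep(ys - cy, times = length(xs))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u * u + v * v <= 1
  yy <- rep(ys, times = length(xs))
  xx <- rep(xs, each = length(ys))
  yy[inside] + (xx[inside] - 1L) * height
}

#' Render one synthetic gland tile
#'
#' Deterministically renders the tile described by a [synthetic_spec()]:
#' glands are randomly rotated ellipses with an inner lumen ellipse,
#' placed by rejection sampling (at most 100 attempts per gland; glands
#' that cannot be placed without overlap are skipped). The mask marks the
#' whole gland (epithelial ring plus lumen) as 1.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `labeled_tile` with elements `image` (height x
#'   width x 3 array of 0-255 intensities), `mask` (height x width matrix
#'   of 0/1), `glands` (data frame of placed ellipse parameters: cx, cy,
#'   a, b, theta) and `spec`.
#' @export
generate_tile <- function(spec) {
  validate_synthetic_spec(spec)
  old_seed <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)

  h <- spec$height
  w <- spec$width
  mask <- matrix(0L, h, w)
  lumen <- matrix(0L, h, w)
  placed <- list()
  for (g in seq_len(spec$n_glands)) {
    for (attempt in seq_len(100L)) {
      a <- stats::runif(1, spec$radius_range[1L], spec$radius_range[2L])
      b <- a * stats::runif(1, spec$axis_ratio[1L], spec$axis_ratio[2L])
      theta <- stats::runif(1, 0, pi)
      m <- ceiling(max(a, b)) + 1
      if (2 * m >= w || 2 * m >= h) next
      cx <- stats::runif(1, m, w - m)
      cy <- stats::runif(1, m, h - m)
      px <- ellipse_pixels(cx, cy, a, b, theta, w, h)
      if (any(mask[px] == 1L)) next
      mask[px] <- 1L
      lp <- ellipse_pixels(cx, cy, a * spec$lumen_ratio, b * spec$lumen_ratio,
                           theta, w, h)
      lumen[lp] <- 1L
      placed[[length(placed) + 1L]] <- c(cx = cx, cy = cy, a = a, b = b,
                                         theta = theta)
      break
    }
  }

  image <- array(0, dim = c(h, w, 3L))
  for (ch in 1:3) {
    plane <- matrix(spec$palette$stroma[ch], h, w)
    plane[mask == 1L] <- spec$palette$epithelium[ch]
    plane[lumen == 1L] <- spec$palette$lumen[ch]
    image[, , ch] <- plane
  }
  if (spec$noise_sigma > 0) {
    image <- image + stats::rnorm(length(image), sd = spec$noise_sigma)
  }
  image <- round(clamp(image, 0, 255))

  glands <- if (length(placed)) {
    as.data.frame(do.call(rbind, placed))
  } else {
    data.frame(cx = numeric(0), cy = numeric(0), a = numeric(0),
               b = numeric(0), theta = numeric(0))
  }
  structure(list(image = image, mask = mask, glands = glands, spec = spec),
            class = "labeled_tile")
}

#' Write a set of synthetic tiles to disk
#'
#' Renders each spec with [generate_tile()] and writes the image and mask
#' as 8-bit PNG files (mask stored with values 0/255) plus a CSV manifest.
#'
#' @param spec_list List of [synthetic_spec()] objects.
#' @param out_dir Output directory (created if needed).
#' @return Data frame manifest with columns image_path, mask_path, width,
#'   height, seed (also written as `manifest.csv` in `out_dir`).
#' @export
generate_dataset <- function(spec_list, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop_maaseg("cannot create output directory: ", out_dir,
                  class = "maaseg_io_error")
    }
  }
  rows <- vector("list", length(spec_list))
  for (k in seq_along(spec_list)) {
    spec <- spec_list[[k]]
    tile <- generate_tile(spec)
    img_path <- file.path(out_dir, sprintf("tile_%04d.png", k))
    msk_path <- file.path(out_dir, sprintf("tile_%04d_mask.png", k))
    write_image_png(tile$image, img_path)
    png::writePNG(tile$mask * 1.0, msk_path)
    rows[[k]] <- data.frame(image_path = img_path, mask_path = msk_path,
                            width = spec$width, height = spec$height,
                            seed = spec$seed, stringsAsFactors = FALSE)
  }
  manifest <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(image_path = character(0), mask_path = character(0),
               width = integer(0), height = integer(0), seed = integer(0))
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

# ---- image I/O --------------------------------------------------------------

#' Read an RGB image as a 0-255 array
#' @param path PNG file path.
#' @return height x width x 3 numeric array on the 0-255 scale.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop_maaseg("image file not found: ", path, class = "maaseg_io_error")
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), dim = c(dim(a), 3L))
  round(a[, , 1:3, drop = FALSE] * 255)
}

#' Read a binary mask PNG (values 0/255 on disk) as a 0/1 matrix
#' @param path PNG file path.
#' @return height x width integer matrix with values 0/1.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    stop_maaseg("mask file not found: ", path, class = "maaseg_io_error")
  }
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  m <- matrix(as.integer(a > 0.5), nrow(a), ncol(a))
  m
}

write_image_png <- function(image, path) {
  png::writePNG(clamp(image, 0, 255) / 255, path)
}

#' Write a 0/1 mask as a PNG with on-disk values 0/255
#' @param mask 0/1 matrix.
#' @param path Output path.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1.0, path)
}
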