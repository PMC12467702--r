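#' Sliding-window patch grid over a whole-slide image
#'
#' Computes the top-left coordinates of all `patch_size` x `patch_size`
#' windows at the given stride, with a final start clamped to
#' `dimension - patch_size` so the full image is covered (the tail window
#' is kept even when the dimension is not a multiple of the stride).
#' Coordinates are 0-based; patches are half-open `[x, x + patch_size)`.
#'
#' @param W,H Image width and height in pixels.
#' @param patch_size Patch side length (default 112).
#' @param stride Step between consecutive windows (default 56, i.e. 50%
#'   overlap).
#' @return A list of class `patch_grid` with `starts_x`, `starts_y`
#'   (0-based), `n`, and the grid geometry.
#' @export
compute_patch_grid <- function(W, H, patch_size = 112L, stride = 56L) {
  W <- as.integer(W); H <- as.integer(H)
  patch_size <- as.integer(patch_size); stride <- as.integer(stride)
  if (W < patch_size || H < patch_size) {
    stop_maaseg("image (", W, "x", H, ") smaller than patch size ",
                patch_size, class = "maaseg_dimension_error")
  }
  axis_starts <- function(dim) {
    s <- seq.int(0L, dim - patch_size, by = stride)
    sort(unique(c(s, dim - patch_size)))
  }
  sx <- axis_starts(W)
  sy <- axis_starts(H)
  structure(list(W = W, H = H, patch_size = patch_size, stride = stride,
                 starts_x = sx, starts_y = sy,
                 n = length(sx) * length(sy)),
            class = "patch_grid")
}

#' Crop an image into the patches of a grid
#'
#' @param image Matrix (H x W) or array (H x W x C).
#' @param grid A [compute_patch_grid()] result matching the image size.
#' @return List of length `grid$n`; each element has `x`, `y` (0-based
#'   top-left) and `data` (the patch, same number of channels as input).
#'   Patch order is x-major (all y for the first x, then the next x).
#' @export
crop_patches <- function(image, grid) {
  d <- dim(image)
  if (d[1L] != grid$H || d[2L] != grid$W) {
    stop_maaseg("image dims ", d[2L], "x", d[1L], " do not match grid ",
                grid$W, "x", grid$H, class = "maaseg_dimension_error")
  }
  ps <- grid$patch_size
  out <- vector("list", grid$n)
  k <- 0L
  for (x in grid$starts_x) for (y in grid$starts_y) {
    k <- k + 1L
    patch <- if (length(d) == 2L) {
      image[y + seq_len(ps), x + seq_len(ps), drop = FALSE]
    } else {
      image[y + seq_len(ps), x + seq_len(ps), , drop = FALSE]
    }
    out[[k]] <- list(x = x, y = y, data = patch)
  }
  out
}

#' Image-level label of a mask patch
#'
#' A patch is labeled with a two-bit vector: `gland = 1` iff any pixel of
#' the binary mask patch is foreground, `background = 1` iff any pixel is
#' background.
#'
#' @param mask_patch Binary (0/1) matrix.
#' @return Named integer vector `c(gland =, background =)`.
#' @export
derive_image_labels <- function(mask_patch) {
  if (!is_binary_mask(mask_patch)) {
    stop_maaseg("mask patch must be binary 0/1", class = "maaseg_value_error")
  }
  c(gland = as.integer(any(mask_patch == 1)),
    background = as.integer(any(mask_patch == 0)))
}

#' Stitch per-patch score rasters back to full size
#'
#' Overlapping pixels receive the arithmetic mean of all contributing
#' patch scores.
#'
#' @param patch_scores List of per-patch matrices (or H x W x C arrays),
#'   one per grid cell, in [crop_patches()] order.
#' @param grid The [compute_patch_grid()] used to crop.
#' @return Matrix (or array) of size `grid$H` x `grid$W` (x C).
#' @export
stitch_patches <- function(patch_scores, grid) {
  if (length(patch_scores) != grid$n) {
    stop_maaseg("got ", length(patch_scores), " patches, grid has ", grid$n,
                class = "maaseg_dimension_error")
  }
  ps <- grid$patch_size
  d1 <- dim(patch_scores[[1L]])
  nc <- if (length(d1) == 3L) d1[3L] else 1L
  acc <- array(0, dim = c(grid$H, grid$W, nc))
  cnt <- matrix(0, grid$H, grid$W)
  k <- 0L
  for (x in grid$starts_x) for (y in grid$starts_y) {
    k <- k + 1L
    p <- patch_scores[[k]]
    if (length(dim(p)) == 2L) dim(p) <- c(ps, ps, 1L)
    acc[y + seq_len(ps), x + seq_len(ps), ] <-
      acc[y + seq_len(ps), x + seq_len(ps), , drop = FALSE] + p
    cnt[y + seq_len(ps), x + seq_len(ps)] <-
      cnt[y + seq_len(ps), x + seq_len(ps)] + 1
  }
  for (c in seq_len(nc)) acc[, , c] <- acc[, , c] / cnt
  if (nc == 1L) matrix(acc, grid$H, grid$W) else acc
}

#' Build a patch manifest for a set of tiles
#'
#' Crops every image/mask pair of a tile manifest into grid patches,
#' writes patch PNGs, and records per-patch image-level labels.
#'
#' @param tile_manifest Data frame with columns `image_path`, `mask_path`.
#' @param out_dir Directory for patch PNGs and the manifest CSV.
#' @param patch_size,stride Grid parameters.
#' @return Data frame with columns image_path, mask_path, tile, x, y,
#'   gland_bit, background_bit.
#' @export
tile_dataset <- function(tile_manifest, out_dir, patch_size = 112L,
                         stride = 56L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  rows <- list()
  for (i in seq_len(nrow(tile_manifest))) {
    img <- read_image(tile_manifest$image_path[i])
    msk <- read_mask(tile_manifest$mask_path[i])
    grid <- compute_patch_grid(ncol(msk), nrow(msk), patch_size, stride)
    pi_ <- crop_patches(img, grid)
    pm_ <- crop_patches(msk, grid)
    for (k in seq_along(pi_)) {
      lab <- derive_image_labels(pm_[[k]]$data)
      ip <- file.path(out_dir, sprintf("t%03d_x%04d_y%04d.png", i,
                                       pi_[[k]]$x, pi_[[k]]$y))
      mp <- file.path(out_dir, sprintf("t%03d_x%04d_y%04d_mask.png", i,
                                       pi_[[k]]$x, pi_[[k]]$y))
      write_image_png(pi_[[k]]$data, ip)
      write_mask(pm_[[k]]$data, mp)
      rows[[length(rows) + 1L]] <- data.frame(
        image_path = ip, mask_path = mp, tile = i,
        x = pi_[[k]]$x, y = pi_[[k]]$y,
        gland_bit = lab[["gland"]], background_bit = lab[["background"]],
        stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "patches.csv"),
                   row.names = FALSE)
  manifest
}
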