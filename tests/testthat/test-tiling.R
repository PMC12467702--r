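test_that("patch grids reproduce the GlaS whole-slide counts", {
  expect_equal(compute_patch_grid(775, 522)$n, 117L)   # 13 x 9
  expect_equal(compute_patch_grid(589, 453)$n, 80L)    # 10 x 8
  expect_equal(compute_patch_grid(574, 433)$n, 70L)    # 10 x 7
  g <- compute_patch_grid(112, 112)
  expect_equal(g$n, 1L)
  expect_equal(g$starts_x, 0L)
  expect_equal(g$starts_y, 0L)
  expect_error(compute_patch_grid(100, 200), class = "maaseg_dimension_error")
})

test_that("grid counts match exhaustive enumeration and cover the image", {
  set.seed(42)
  for (i in 1:250) {
    W <- sample(112:1024, 1); H <- sample(112:1024, 1)
    g <- compute_patch_grid(W, H)
    expect_equal(g$n, oracle_grid_count(W, H))
    # clamped tail start and coverage
    expect_equal(max(g$starts_x), W - 112L)
    expect_equal(max(g$starts_y), H - 112L)
    covered_x <- rep(FALSE, W)
    for (x in g$starts_x) covered_x[x + 1:112] <- TRUE
    expect_true(all(covered_x))
  }
})

test_that("crop produces grid-sized patches that stitch back losslessly", {
  set.seed(7)
  img <- matrix(runif(231 * 175), 175, 231)
  g <- compute_patch_grid(231, 175)
  patches <- crop_patches(img, g)
  expect_length(patches, g$n)
  expect_true(all(vapply(patches, function(p) all(dim(p$data) == c(112, 112)),
                         logical(1))))
  # crop -> stitch is lossless for any raster (mean of identical overlaps)
  rec <- stitch_patches(lapply(patches, `[[`, "data"), g)
  expect_equal(rec, img, tolerance = 1e-12)
  expect_error(crop_patches(img[1:100, ], g), class = "maaseg_dimension_error")
  expect_error(stitch_patches(lapply(patches[-1], `[[`, "data"), g),
               class = "maaseg_dimension_error")
})

test_that("overlapping patches average their scores when stitched", {
  g <- compute_patch_grid(168, 112)   # two patches, 56 shared columns
  p0 <- matrix(0, 112, 112)
  p1 <- matrix(1, 112, 112)
  st <- stitch_patches(list(p0, p1), g)
  expect_true(all(st[, 1:56] == 0))
  expect_true(all(st[, 57:112] == 0.5))
  expect_true(all(st[, 113:168] == 1))
})

test_that("image-level labels follow the any-pixel rule", {
  expect_equal(derive_image_labels(matrix(1, 4, 4)),
               c(gland = 1L, background = 0L))
  m <- matrix(0, 4, 4); m[1, 1] <- 1
  expect_equal(derive_image_labels(m), c(gland = 1L, background = 1L))
  expect_equal(derive_image_labels(matrix(0, 4, 4)),
               c(gland = 0L, background = 1L))
  expect_error(derive_image_labels(matrix(0.5, 2, 2)),
               class = "maaseg_value_error")
})

test_that("tile_dataset writes a labeled patch manifest", {
  out <- file.path(tempdir(), "tiling_ds")
  unlink(out, recursive = TRUE)
  man <- generate_dataset(list(tiny_spec(seed = 3, width = 168, height = 168)),
                          file.path(out, "tiles"))
  pm <- tile_dataset(man, file.path(out, "patches"))
  expect_equal(nrow(pm), 4L)   # 2 x 2 grid at 168
  expect_true(all(file.exists(pm$image_path)))
  expect_true(all(pm$gland_bit %in% 0:1 & pm$background_bit %in% 0:1))
  expect_true(all(pm$gland_bit | pm$background_bit))
})
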