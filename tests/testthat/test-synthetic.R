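test_that("generate_tile is a pure function of its spec", {
  spec <- tiny_spec(seed = 11, n_glands = 3)
  a <- generate_tile(spec)
  b <- generate_tile(spec)
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  # the global RNG stream is untouched
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(generate_tile(spec)); after <- runif(3)
  expect_identical(before, after)
})

test_that("gland-free specs yield empty masks and pure stroma", {
  tl <- generate_tile(tiny_spec(seed = 2, n_glands = 0))
  expect_true(all(tl$mask == 0))
  pal <- tl$spec$palette
  for (ch in 1:3) expect_true(all(tl$image[, , ch] == pal$stroma[ch]))
})

test_that("noiseless tiles color every pixel from the palette per its class", {
  tl <- generate_tile(tiny_spec(seed = 5, n_glands = 2, noise_sigma = 0))
  pal <- tl$spec$palette
  cols <- apply(do.call(cbind, lapply(1:3, function(ch) as.vector(tl$image[, , ch]))),
                1L, paste, collapse = "_")
  key <- function(v) paste(v, collapse = "_")
  gland_cols <- unique(cols[as.vector(tl$mask) == 1])
  stroma_cols <- unique(cols[as.vector(tl$mask) == 0])
  expect_true(all(gland_cols %in% c(key(pal$epithelium), key(pal$lumen))))
  expect_identical(stroma_cols, key(pal$stroma))
  # with zero noise the three classes are exactly three distinct RGB points
  expect_lte(length(unique(cols)), 3L)
})

test_that("placed-ellipse bookkeeping bounds the gland pixel fraction", {
  spec <- synthetic_spec(seed = 1, width = 775, height = 522, n_glands = 6,
                         radius_range = c(30, 60))
  tl <- generate_tile(spec)
  frac <- mean(tl$mask)
  expect_gt(frac, 0.02)
  expect_lt(frac, 0.6)
  # brute-force area bound from the recorded ellipse parameters
  area_bound <- sum(pi * tl$glands$a * tl$glands$b) / (775 * 522)
  expect_lte(frac, area_bound * 1.05)
  expect_gte(frac, area_bound * 0.5)
})

test_that("generate_dataset writes images, masks and a manifest that round-trip", {
  out <- file.path(tempdir(), "synth_ds")
  unlink(out, recursive = TRUE)
  specs <- lapply(1:3, function(k) tiny_spec(seed = k))
  man <- generate_dataset(specs, out)
  expect_equal(nrow(man), 3L)
  expect_true(all(file.exists(man$image_path)))
  expect_true(all(file.exists(man$mask_path)))
  tl <- generate_tile(specs[[2]])
  expect_equal(read_image(man$image_path[2]), tl$image, ignore_attr = TRUE)
  expect_identical(read_mask(man$mask_path[2]), tl$mask)
  # regenerating yields byte-identical files
  h1 <- tools::md5sum(c(man$image_path, man$mask_path))
  man2 <- generate_dataset(specs, out)
  h2 <- tools::md5sum(c(man2$image_path, man2$mask_path))
  expect_identical(unname(h1), unname(h2))
})

test_that("empty spec lists and invalid specs are handled", {
  out <- file.path(tempdir(), "synth_empty")
  unlink(out, recursive = TRUE)
  man <- generate_dataset(list(), out)
  expect_equal(nrow(man), 0L)
  expect_length(list.files(out, pattern = "\\.png$"), 0L)
  expect_error(synthetic_spec(width = 64), class = "maaseg_config_error")
  expect_error(synthetic_spec(lumen_ratio = 1.2), class = "maaseg_config_error")
  expect_error(synthetic_spec(radius_range = c(1, 10)),
               class = "maaseg_config_error")
})
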