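test_that("the feature pyramid follows the 1/4..1/128 ceiling-division shape law", {
  set.seed(1)
  enc <- maaseg:::encoder_new(encoder_config("tiny"))
  model <- structure(list(encoder = enc, norm = NULL), class = "maf_model")
  img <- array(runif(112 * 112 * 3) * 255, c(112, 112, 3))
  pyr <- encode(model, img)
  expect_length(pyr, 6L)
  expect_equal(vapply(pyr, `[[`, integer(1), "h"), c(28L, 14L, 7L, 4L, 2L, 1L))
  expect_equal(vapply(pyr, function(p) dim(p$map)[3L], integer(1)),
               c(8L, 16L, 24L, 32L, 40L, 48L))
  img2 <- array(runif(128 * 128 * 3) * 255, c(128, 128, 3))
  pyr2 <- encode(model, img2)
  expect_equal(vapply(pyr2, `[[`, integer(1), "h"), c(32L, 16L, 8L, 4L, 2L, 1L))
  # general law: ceiling of previous dims / stride
  img3 <- array(runif(150 * 117 * 3), c(150, 117, 3))
  pyr3 <- encode(model, img3)
  h <- 150; for (i in 1:6) {
    h <- ceiling(h / maaseg:::encoder_config("tiny")$strides[i])
    expect_equal(pyr3[[i]]$h, as.integer(h))
  }
  expect_error(encode(model, array(0, c(8, 8, 3))),
               class = "maaseg_dimension_error")
})

test_that("encode is deterministic for fixed parameters", {
  set.seed(3)
  enc <- maaseg:::encoder_new(encoder_config("tiny"))
  model <- structure(list(encoder = enc, norm = NULL), class = "maf_model")
  img <- array(runif(112 * 112 * 3) * 255, c(112, 112, 3))
  expect_identical(encode(model, img)[[3]]$map, encode(model, img)[[3]]$map)
})

test_that("overlapping patch merging downsamples by ceiling division", {
  set.seed(2)
  x <- array(rnorm(32 * 32 * 4), c(32, 32, 4))
  expect_equal(dim(overlap_patch_merge(x, 2L, 6L)), c(16L, 16L, 6L))
  y <- array(rnorm(7 * 7 * 2), c(7, 7, 2))
  expect_equal(dim(overlap_patch_merge(y, 2L, 3L)), c(4L, 4L, 3L))
  # six-layer ladder from 112
  sizes <- integer(0); cur <- array(rnorm(112 * 112 * 3), c(112, 112, 3))
  strides <- c(4L, 2L, 2L, 2L, 2L, 2L)
  for (s in strides) {
    cur <- overlap_patch_merge(cur, s, 4L)
    sizes <- c(sizes, dim(cur)[1L])
  }
  expect_equal(sizes, c(28L, 14L, 7L, 4L, 2L, 1L))
  expect_error(overlap_patch_merge(x, 3L, 4L), class = "maaseg_config_error")
})

test_that("attention weights are row-stochastic and respect the residual", {
  set.seed(4)
  x <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  p <- maaseg:::new_attention(8L, 2L)
  out <- attention_block(x, heads = 2L, reduction = 1L, weights = p)
  expect_equal(dim(out), dim(x))
  for (A in attr(out, "attention")) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-12)
  }
  # zeroed value path (with nonzero output projection) leaves the input
  p$v$W$value[] <- 0; p$v$b$value[] <- 0
  p$o$W$value <- matrix(rnorm(64), 8, 8)
  out0 <- attention_block(x, heads = 2L, reduction = 1L, weights = p)
  expect_equal(unclass(out0), x, ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(maaseg:::new_attention(8L, 3L), class = "maaseg_config_error")
})

test_that("full attention is equivariant to spatial permutations", {
  set.seed(5)
  h <- 3L; w <- 3L; C <- 8L
  x <- array(rnorm(h * w * C), c(h, w, C))
  p <- maaseg:::new_attention(C, 2L)
  p$o$W$value <- matrix(rnorm(C * C, sd = 0.3), C, C)   # activate the branch
  perm <- sample(h * w)
  xm <- maaseg:::raster_to_mat(x)
  xp <- maaseg:::mat_to_raster(xm[perm, , drop = FALSE], h, w)
  out <- maaseg:::raster_to_mat(attention_block(x, 2L, 1L, weights = p))
  outp <- maaseg:::raster_to_mat(attention_block(xp, 2L, 1L, weights = p))
  expect_equal(outp, out[perm, , drop = FALSE], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Mix-FFN preserves shape, starts as the identity, and is shift-covariant", {
  set.seed(6)
  x <- array(rnorm(5 * 7 * 8), c(5, 7, 8))
  p <- maaseg:::new_mixffn(8L)
  # zero-initialized contraction: residual branch silent at init
  expect_equal(mix_ffn_block(x, weights = p), x, tolerance = 1e-12)
  p$fc2$W$value <- matrix(rnorm(32 * 8, sd = 0.2), 32, 8)
  out <- mix_ffn_block(x, weights = p)
  expect_equal(dim(out), dim(x))
  expect_gt(max(abs(out - x)), 0)
  # translation of an interior pattern translates the interior response
  big <- array(0.5, c(16, 16, 8))
  pat <- array(rnorm(3 * 3 * 8), c(3, 3, 8))
  a <- big; a[6:8, 6:8, ] <- pat
  b <- big; b[7:9, 7:9, ] <- pat
  fa <- mix_ffn_block(a, weights = p)
  fb <- mix_ffn_block(b, weights = p)
  expect_equal(fa[4:10, 4:10, ], fb[5:11, 5:11, ], tolerance = 1e-10)
})
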