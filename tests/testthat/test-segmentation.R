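test_that("the segmentation network emits full-resolution two-class logits", {
  set.seed(1)
  model <- psp_new()
  model$norm <- list(mean = rep(0.5, 3), sd = rep(0.2, 3))
  img <- array(runif(64 * 64 * 3) * 255, c(64, 64, 3))
  lg <- psp_forward(model, img)
  expect_equal(dim(lg), c(64L, 64L, 2L))
  # doubling the input size doubles the output size
  img2 <- array(runif(128 * 128 * 3) * 255, c(128, 128, 3))
  expect_equal(dim(psp_forward(model, img2)), c(128L, 128L, 2L))
  # deterministic forward
  expect_identical(psp_forward(model, img), lg)
  mask <- segment_image(model, img)
  expect_true(all(mask %in% 0:1))
})

test_that("per-pixel cross-entropy matches hand-computed softmax values", {
  lg <- array(0, c(1, 2, 2))
  lg[1, 1, ] <- c(0, 0)          # uniform: loss ln 2 at either label
  lg[1, 2, ] <- c(log(3), 0)     # softmax (0.75, 0.25)
  mask <- matrix(c(0L, 0L), 1, 2)
  lm <- pixel_ce(lg, mask)
  expect_equal(lm[1, 1], log(2), tolerance = 1e-12)
  expect_equal(lm[1, 2], log(4 / 3), tolerance = 1e-12)
  mask2 <- matrix(c(0L, 1L), 1, 2)
  expect_equal(pixel_ce(lg, mask2)[1, 2], log(4), tolerance = 1e-12)
  # 255 pixels are excluded and insensitive to their logits
  mask3 <- matrix(c(0L, 255L), 1, 2)
  lm3 <- pixel_ce(lg, mask3)
  expect_true(is.na(lm3[1, 2]))
  lg_flip <- lg; lg_flip[1, 2, ] <- c(-50, 99)
  expect_equal(pixel_ce(lg_flip, mask3)[1, 1], lm3[1, 1])
  expect_equal(normalized_loss(lg, mask3), normalized_loss(lg_flip, mask3))
  expect_error(pixel_ce(lg, matrix(255L, 1, 2)), class = "maaseg_value_error")
})

test_that("OEEM weights are the normalized softmax of negated losses", {
  # uniform losses: every weight is exactly 1
  lm <- matrix(0.7, 3, 4)
  expect_true(all(abs(oeem_weights(lm) - 1) < 1e-12))
  # two pixels with losses (0, ln 2): softmax(-L) = (2/3, 1/3) -> w = (4/3, 2/3)
  w <- oeem_weights(c(0, log(2)))
  expect_equal(w, c(4 / 3, 2 / 3), tolerance = 1e-12)
  # mean exactly 1, NAs preserved, low loss up-weighted
  set.seed(4)
  for (i in 1:20) {
    lm <- matrix(rexp(30), 5, 6)
    lm[sample(30, 5)] <- NA
    w <- oeem_weights(lm)
    expect_equal(mean(w, na.rm = TRUE), 1, tolerance = 1e-9)
    expect_identical(is.na(w), is.na(lm))
    expect_true(all(w[!is.na(w)] > 0))
  }
})

test_that("the normalized loss switches between weighted and plain cross-entropy", {
  # single-class mask: exactly the mean cross-entropy
  set.seed(5)
  lg <- array(rnorm(8 * 8 * 2), c(8, 8, 2))
  mask1 <- matrix(1L, 8, 8)
  expect_equal(normalized_loss(lg, mask1), mean(pixel_ce(lg, mask1)),
               tolerance = 1e-12)
  # worked two-pixel value: (4/3 * 0 + 2/3 * ln 2) / 2 = ln 2 / 3
  lg2 <- array(0, c(1, 2, 2))
  lg2[1, 1, ] <- c(50, 0)        # ~zero loss at label 0
  lg2[1, 2, ] <- c(log(2), 0)    # loss ln 2 ... constructed below instead
  # build exactly losses (0, ln2): uniform logits give ln2; a huge margin gives 0
  mask2 <- matrix(c(0L, 0L), 1, 2)
  lgx <- array(0, c(1, 2, 2)); lgx[1, 1, ] <- c(60, 0)
  lm <- pixel_ce(lgx, mask2)
  expect_equal(lm[1, 2], log(2), tolerance = 1e-12)
  expect_equal(lm[1, 1], 0, tolerance = 1e-12)
  # two distinct classes trigger the weighted branch
  mask_mixed <- matrix(c(0L, 1L), 1, 2)
  lgm <- array(0, c(1, 2, 2)); lgm[1, 1, ] <- c(60, 0); lgm[1, 2, ] <- c(0, 0)
  lmm <- pixel_ce(lgm, mask_mixed)
  expect_equal(as.vector(lmm), c(0, log(2)), tolerance = 1e-12)
  expect_equal(normalized_loss(lgm, mask_mixed), log(2) / 3, tolerance = 1e-9)
  # equal losses with n > 1 classes: weights are 1, equals the plain mean
  lge <- array(0, c(1, 2, 2))
  expect_equal(normalized_loss(lge, mask_mixed), log(2), tolerance = 1e-12)
  # never negative for a perfect prediction
  expect_gte(normalized_loss(lgm, matrix(c(0L, 255L), 1, 2)), 0)
})

test_that("segmentation training runs, reproduces, and respects the manifest", {
  out <- file.path(tempdir(), "seg_train")
  unlink(out, recursive = TRUE)
  dir.create(out)
  set.seed(2)
  paths <- list()
  for (k in 1:4) {
    tl <- generate_tile(tiny_spec(seed = k))
    ip <- file.path(out, sprintf("img%d.png", k))
    pp <- file.path(out, sprintf("pl%d.png", k))
    maaseg:::write_image_png(tl$image, ip)
    pl <- tl$mask
    pl[sample(length(pl), 500)] <- 255L   # some ignored pixels
    write_pseudo(pl, pp)
    paths[[k]] <- data.frame(image_path = ip, pseudo_path = pp)
  }
  pmg <- do.call(rbind, paths)
  cfg <- list(iterations = 6L, batch_size = 2L, seed = 3L, log_every = 2L)
  fit1 <- train_seg_stage(pmg, cfg)
  expect_true(all(is.finite(fit1$log$loss)))
  fit2 <- train_seg_stage(pmg, cfg)
  expect_identical(fit1$log$loss, fit2$log$loss)
  expect_error(train_seg_stage(pmg[0, ], cfg), class = "maaseg_value_error")
})
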