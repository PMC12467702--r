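test_that("align_feature upsamples bilinearly and projects channels", {
  set.seed(1)
  Fi <- array(rnorm(4 * 4 * 5), c(4, 4, 5))
  # already at target resolution with the identity projection: unchanged
  expect_equal(align_feature(Fi, c(4, 4)), Fi, tolerance = 1e-12)
  # constants stay constant under bilinear interpolation and a projection
  Fc <- array(2, c(3, 3, 2))
  w <- list(W = matrix(c(1, 0.5, -1, 2), 2, 2), b = c(0.1, -0.2))
  out <- align_feature(Fc, c(9, 9), weights = w)
  expect_equal(dim(out), c(9L, 9L, 2L))
  expect_true(all(abs(out[, , 1] - (2 * 1 + 2 * 0.5 + 0.1)) < 1e-12))
  # 2x2 -> 4x4 against a hand-rolled align-corners bilinear oracle
  m <- array(c(0, 1, 1, 0), c(2, 2, 1))
  got <- align_feature(m, c(4, 4))[, , 1]
  src <- 1 + (0:3) * (1 / 3)
  expected <- matrix(0, 4, 4)
  for (i in 1:4) for (j in 1:4) {
    y <- src[i]; x <- src[j]
    y0 <- floor(y); x0 <- floor(x)
    fy <- y - y0; fx <- x - x0
    y1 <- min(y0 + 1, 2); x1 <- min(x0 + 1, 2)
    expected[i, j] <- m[y0, x0, 1] * (1 - fy) * (1 - fx) +
      m[y1, x0, 1] * fy * (1 - fx) +
      m[y0, x1, 1] * (1 - fy) * fx + m[y1, x1, 1] * fy * fx
  }
  expect_equal(got, expected, tolerance = 1e-12)
  expect_equal(got[1, 1], 0)  # corners preserved
  expect_equal(got[1, 4], 1)
})

test_that("fusion is an element-wise sum over identically shaped maps", {
  set.seed(2)
  a <- array(rnorm(12), c(2, 2, 3))
  b <- array(rnorm(12), c(2, 2, 3))
  c3 <- array(rnorm(12), c(2, 2, 3))
  expect_equal(fuse(a, b, c3), a + b + c3)
  expect_equal(fuse(a, b, c3), fuse(c3, a, b))
  z <- array(0, c(2, 2, 3))
  expect_equal(fuse(z, z, z), z)
  one <- array(1, c(2, 2, 3))
  expect_equal(fuse(one, 2 * one, 3 * one)[1, 1, 1], 6)
  expect_error(fuse(a, array(0, c(3, 2, 3))), class = "maaseg_dimension_error")
})

test_that("classification pools the per-position head response", {
  set.seed(3)
  model <- maf_new()
  Fm <- array(rnorm(7 * 7 * 32), c(7, 7, 32))
  model$head$W$value[] <- 0
  model$head$b$value[] <- 0
  expect_equal(unname(classify(model, Fm)), c(0, 0))
  # uniform score raster pools to itself
  model$head$W$value[] <- 0
  model$head$b$value <- c(0.7, -0.3)
  expect_equal(unname(classify(model, Fm)), c(0.7, -0.3))
  # class-symmetric: permuting head columns permutes logits
  model$head$W$value <- matrix(rnorm(64), 32, 2)
  model$head$b$value <- c(0.1, 0.2)
  l12 <- classify(model, Fm)
  model$head$W$value <- model$head$W$value[, 2:1]
  model$head$b$value <- model$head$b$value[2:1]
  l21 <- classify(model, Fm)
  expect_equal(unname(l21), unname(rev(l12)))
})

test_that("image-label training runs, is seeded-reproducible, and has usable gradients", {
  out <- file.path(tempdir(), "maf_train")
  unlink(out, recursive = TRUE)
  man <- generate_dataset(list(tiny_spec(seed = 1, width = 168, height = 168),
                               tiny_spec(seed = 2, width = 168, height = 168,
                                         n_glands = 0)),
                          file.path(out, "tiles"))
  pm <- tile_dataset(man, file.path(out, "patches"))
  cfg <- list(epochs = 2L, batch_size = 4L, seed = 5L)
  fit1 <- train_cam_stage(pm, cfg)
  expect_true(all(is.finite(fit1$log$loss)))
  expect_equal(nrow(fit1$log), 2L)
  fit2 <- train_cam_stage(pm, cfg)
  expect_identical(fit1$log$loss, fit2$log$loss)   # same seed, same trajectory
  # loss decreased from a mismatched-label gradient signal
  expect_lt(fit1$log$loss[2], fit1$log$loss[1])
  expect_error(train_cam_stage(pm[0, ], cfg), class = "maaseg_value_error")
  # predicted bits have the right form
  bits <- predict_image_labels(fit1$model, read_image(pm$image_path[1]))
  expect_true(all(bits %in% 0:1))
})

test_that("class activation maps are rectified, normalized and well-shaped", {
  set.seed(9)
  model <- maf_new()
  model$norm <- list(mean = rep(0.5, 3), sd = rep(0.25, 3))
  img <- array(runif(112 * 112 * 3) * 255, c(112, 112, 3))
  cam <- generate_cam(model, img)
  expect_s3_class(cam, "class_activation_map")
  expect_equal(dim(cam$scores), c(7L, 7L, 2L))
  expect_true(all(cam$scores >= 0 & cam$scores <= 1))
  expect_named(cam$logits, c("gland", "background"))
  up <- generate_cam(model, img, out_size = c(112, 112))
  expect_equal(dim(up$scores), c(112L, 112L, 2L))
  expect_true(all(up$scores >= 0 & up$scores <= 1))
  # degenerate range rule: a zero head yields an all-zero map, not NaN
  model$head$W$value[] <- 0
  model$head$b$value[] <- 0
  cam0 <- generate_cam(model, img)
  expect_true(all(cam0$scores == 0))
})
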