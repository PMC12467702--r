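test_that("IoU and Dice match their set definitions", {
  a <- matrix(0L, 10, 20); a[1:5, 1:20] <- 1L       # |A| = 100
  b <- matrix(0L, 10, 20); b[3:7, 1:20] <- 1L       # |B| = 100, overlap 60
  expect_equal(iou(a, b), 60 / 140)
  expect_equal(dice(a, b), 120 / 200)
  expect_equal(iou(a, a), 1)
  expect_equal(dice(a, a), 1)
  d <- matrix(0L, 10, 20); d[8:10, ] <- 1L          # disjoint from a
  expect_equal(iou(a, d), 0)
  expect_equal(dice(a, d), 0)
  # |X| = |Y| = 100 with overlap 50 -> IoU 1/3, Dice 1/2
  x <- matrix(0L, 10, 20); x[, 1:10] <- 1L
  y <- matrix(0L, 10, 20); y[, 6:15] <- 1L
  expect_equal(iou(x, y), 1 / 3)
  expect_equal(dice(x, y), 0.5)
  # empty-vs-empty convention
  z <- matrix(0L, 4, 4)
  expect_equal(iou(z, z), 1)
  expect_equal(dice(z, z), 1)
  expect_error(iou(a, matrix(0L, 3, 3)), class = "maaseg_dimension_error")
  expect_error(dice(a, matrix(2L, 10, 20)), class = "maaseg_value_error")
})

test_that("dice_from_iou implements 2 IoU / (1 + IoU) with fixed points", {
  expect_equal(dice_from_iou(0), 0)
  expect_equal(dice_from_iou(1), 1)
  expect_equal(dice_from_iou(1 / 3), 0.5)
  expect_equal(dice_from_iou(81.99, percent = TRUE), 90.10)
  expect_equal(dice_from_iou(77.56, percent = TRUE), 87.36)
  # monotone on [0, 1]
  g <- dice_from_iou(seq(0, 1, by = 0.01))
  expect_true(all(diff(g) > 0))
  expect_error(dice_from_iou(1.2), class = "maaseg_value_error")
})

test_that("evaluation pairs masks by id and reports mean and sd in percent", {
  base <- file.path(tempdir(), "eval_masks")
  unlink(base, recursive = TRUE)
  pd <- file.path(base, "pred"); td <- file.path(base, "truth")
  dir.create(pd, recursive = TRUE); dir.create(td, recursive = TRUE)
  x <- matrix(0L, 10, 20); x[, 1:10] <- 1L
  y <- matrix(0L, 10, 20); y[, 6:15] <- 1L
  write_mask(x, file.path(pd, "a.png")); write_mask(x, file.path(td, "a.png"))
  rep1 <- evaluate_masks(pd, td)
  expect_equal(rep1$mean_iou, 100)
  expect_equal(rep1$std_iou, 0)
  write_mask(x, file.path(pd, "b.png")); write_mask(y, file.path(td, "b.png"))
  rep2 <- evaluate_masks(pd, td)
  expect_equal(rep2$mean_iou, 100 * mean(c(1, 1 / 3)), tolerance = 1e-9)
  expect_equal(round(rep2$mean_iou, 2), 66.67)
  expect_true(all(rep2$per_image$dice >= rep2$per_image$iou))
  file.remove(file.path(td, "b.png"))
  expect_error(evaluate_masks(pd, td), class = "maaseg_value_error")
})

test_that("Dice and IoU satisfy their algebraic identity on random masks", {
  set.seed(77)
  for (i in 1:100) {
    a <- random_mask(9, 11, runif(1, 0.1, 0.9))
    b <- random_mask(9, 11, runif(1, 0.1, 0.9))
    i1 <- iou(a, b)
    expect_equal(dice(a, b), dice_from_iou(i1), tolerance = 1e-15)
    expect_gte(dice(a, b), i1)
    expect_equal(iou(b, a), i1)
    expect_equal(dice(b, a), dice(a, b))
  }
})
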