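test_that("confidence thresholding implements the three-way rule with closed bounds", {
  sc <- array(0, c(1, 6, 2))
  sc[1, , 1] <- c(0.70, 0.20, 0.45, 0.60, 0.30, 0.10)   # gland channel
  sc[1, , 2] <- c(0.10, 0.10, 0.10, 0.10, 0.10, 0.65)   # background channel
  lab <- confidence_labels(sc, 0.3, 0.6)
  expect_equal(as.vector(lab), c(1L, 0L, 255L, 1L, 0L, 0L))
  # argmax can pick the background class above beta_high
  sc2 <- array(c(0.2, 0.9), c(1, 1, 2))
  expect_equal(as.vector(confidence_labels(sc2)), 0L)
  expect_error(confidence_labels(sc, 0.7, 0.6), class = "maaseg_config_error")
  expect_error(confidence_labels(sc, 0, 0.6), class = "maaseg_config_error")
})

test_that("pair sets match the exhaustive double-loop oracle", {
  # worked 3x3 example: center gland, rest background, 4-neighborhood
  lab <- matrix(0L, 3, 3); lab[2, 2] <- 1L
  ps <- build_pair_sets(lab, 1)
  expect_equal(ps$n_neg, 4L)
  expect_equal(ps$n_pos, 8L)
  # uniform map: no negatives, every in-radius pair positive
  uni <- matrix(1L, 5, 4)
  psu <- build_pair_sets(uni, 2)
  oru <- oracle_pair_sets(uni, 2)
  expect_equal(psu$n_neg, 0L)
  expect_equal(psu$n_pos, unname(oru["pos"]))
  # all-uncertain map: both sets empty
  ps255 <- build_pair_sets(matrix(255L, 4, 4), 8)
  expect_equal(ps255$n_pos + ps255$n_neg, 0L)
  # randomized rasters up to 12x12 across radii
  set.seed(31)
  for (i in 1:6) {
    h <- sample(2:12, 1); w <- sample(2:12, 1)
    lab <- matrix(sample(c(0L, 1L, 255L), h * w, replace = TRUE), h, w)
    for (r in c(1, 2.5, 8)) {
      ps <- build_pair_sets(lab, r)
      or <- oracle_pair_sets(lab, r)
      expect_equal(c(pos = ps$n_pos, neg = ps$n_neg), or)
      if (ps$n_pos > 0) {
        d2 <- (((ps$pos[, 1] - 1) %% h) - ((ps$pos[, 2] - 1) %% h))^2 +
          (((ps$pos[, 1] - 1) %/% h) - ((ps$pos[, 2] - 1) %/% h))^2
        expect_true(all(d2 <= r^2 & d2 > 0))
      }
    }
  }
})

test_that("the affinity loss matches its worked fixtures and is monotone", {
  lab <- matrix(c(1L, 1L, 0L, 0L), 2, 2)
  ps <- build_pair_sets(lab, 1)         # 2 positives, 2 negatives
  expect_equal(ps$n_pos, 2L)
  expect_equal(ps$n_neg, 2L)
  expect_equal(affinity_loss(rep(0, 4), ps), 1.0)
  ps1 <- build_pair_sets(matrix(c(1L, 255L, 0L, 255L), 2, 2), 1)
  expect_equal(ps1$n_pos + ps1$n_neg, 1L)
  # one positive at ln 3 and one negative at -ln 3: 0.25 + 0.25
  ps2 <- build_pair_sets(matrix(c(1L, 1L, 0L, 255L), 2, 2), 1)
  expect_equal(ps2$n_pos, 1L)
  expect_equal(ps2$n_neg, 1L)
  expect_equal(affinity_loss(c(log(3), -log(3)), ps2), 0.5)
  expect_lt(affinity_loss(c(30, -30), ps2), 1e-8)
  # monotonicity
  base <- affinity_loss(c(0.3, -0.2), ps2)
  expect_lt(affinity_loss(c(0.4, -0.2), ps2), base)
  expect_gt(affinity_loss(c(0.3, -0.1), ps2), base)
  empty <- build_pair_sets(matrix(255L, 2, 2), 1)
  expect_error(affinity_loss(numeric(0), empty), class = "maaseg_value_error")
})

test_that("pair affinity scores are symmetric and zero under a zero head", {
  set.seed(12)
  head <- affinity_head_new(4L)
  feat <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
  lab <- matrix(sample(c(0L, 1L, 255L), 36, replace = TRUE), 6, 6)
  pairs <- cbind(c(1L, 5L, 10L), c(2L, 9L, 30L))
  s_fwd <- pair_affinity(head, feat, lab, pairs)
  s_rev <- pair_affinity(head, feat, lab, pairs[, 2:1])
  expect_equal(s_fwd, s_rev, tolerance = 1e-12)
  head$fc3$W$value[] <- 0
  head$fc3$b$value[] <- 0
  expect_equal(pair_affinity(head, feat, lab, pairs), rep(0, 3))
})

test_that("a trained affinity head separates same-class from cross-class pairs", {
  set.seed(0)
  # synthetic separable case: left half gland, right half background, with
  # features that mirror the split
  sc <- array(0.05, c(8, 8, 2))
  sc[, 1:4, 1] <- 0.95; sc[, 5:8, 2] <- 0.95
  feat <- array(rnorm(8 * 8 * 4, sd = 0.1), c(8, 8, 4))
  feat[, 1:4, 1] <- feat[, 1:4, 1] + 2
  feat[, 5:8, 2] <- feat[, 5:8, 2] + 2
  cam <- structure(list(scores = sc, fused = feat,
                        logits = c(gland = 0, background = 0)),
                   class = "class_activation_map")
  fitted <- train_affinity_stage(list(cam), list(epochs = 40L, seed = 0L,
                                                 refine_scale = 1L,
                                                 label_dropout = 0.5))
  expect_lt(tail(fitted$log$loss, 1), fitted$log$loss[1])
  lab <- confidence_labels(sc)
  same <- cbind(c(1L, 2L), c(9L, 10L))       # within the left block
  cross <- cbind(c(25L, 26L), c(33L, 34L))   # straddling the split
  s_same <- pair_affinity(fitted$head, feat, lab, same)
  s_cross <- pair_affinity(fitted$head, feat, lab, cross)
  expect_gt(min(s_same), max(s_cross))
})

test_that("pixel-adaptive refinement is a range-preserving fixed-point smoother", {
  img <- array(128, c(9, 9, 3))
  sc <- array(0.4, c(9, 9, 2))
  out <- par_refine(img, sc, iterations = 5)
  expect_equal(out, sc, tolerance = 1e-12)
  # a spike inside a uniform color region is strictly attenuated
  sc2 <- array(0, c(9, 9, 1)); sc2[5, 5, 1] <- 1
  out2 <- par_refine(img, sc2, iterations = 10)
  expect_lt(out2[5, 5, 1], 1)
  expect_true(all(out2 >= 0 & out2 <= 1))
  # range bound for arbitrary inputs
  set.seed(5)
  img3 <- array(runif(9 * 9 * 3) * 255, c(9, 9, 3))
  sc3 <- array(runif(81 * 2), c(9, 9, 2))
  out3 <- par_refine(img3, sc3, iterations = 10)
  for (k in 1:2) {
    expect_gte(min(out3[, , k]), min(sc3[, , k]) - 1e-12)
    expect_lte(max(out3[, , k]), max(sc3[, , k]) + 1e-12)
  }
  expect_error(par_refine(img, array(0, c(4, 4, 2))),
               class = "maaseg_dimension_error")
})

test_that("random-walk propagation is stochastic, stable and has the two-pixel limit", {
  # degenerate affinities: transition is the identity
  sc <- array(runif(12), c(2, 3, 2))
  A0 <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                             dims = c(6, 6))
  expect_equal(random_walk(sc, A0, beta = 2, t = 5), sc, tolerance = 1e-12)
  # row-stochastic operator preserves constant maps for arbitrary affinities
  set.seed(8)
  n <- 12
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- sample(nrow(ij), 30)
  A <- Matrix::sparseMatrix(i = c(ij[keep, 1], ij[keep, 2]),
                            j = c(ij[keep, 2], ij[keep, 1]),
                            x = rep(runif(30), 2), dims = c(n, n))
  cmap <- array(0.37, c(3, 4, 2))
  expect_equal(random_walk(cmap, A, beta = 2, t = 7), cmap, tolerance = 1e-12)
  # two pixels with unit affinity converge to the pair mean
  two <- array(c(0.9, 0.1), c(1, 2, 1))
  A2 <- Matrix::sparseMatrix(i = c(1, 2), j = c(2, 1), x = c(1, 1),
                             dims = c(2, 2))
  out <- random_walk(two, A2, beta = 3, t = 40)
  expect_equal(as.vector(out), c(0.5, 0.5), tolerance = 1e-9)
  expect_error(random_walk(two, -A2), class = "maaseg_value_error")
})

test_that("finalized pseudo-labels re-apply the confidence rule at patch scale", {
  hi <- array(0.9, c(4, 4, 2)); hi[, , 2] <- 0.05
  expect_true(all(finalize_pseudo_labels(hi) == 1L))
  lo <- array(0.1, c(4, 4, 2))
  expect_true(all(finalize_pseudo_labels(lo) == 0L))
  up <- finalize_pseudo_labels(hi, out_size = c(16, 16))
  expect_equal(dim(up), c(16L, 16L))
  expect_true(all(up %in% c(0L, 1L, 255L)))
})
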