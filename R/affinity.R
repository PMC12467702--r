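# Affinity refinement: confidence pseudo-labels from CAM scores, learned
# pixel-pair affinities on a local radius, pixel-adaptive refinement (PAR)
# smoothing with RGB+position kernels, and random-walk propagation of the
# class scores through a row-stochastic transition operator.

#' Confidence labels from class activation scores
#'
#' Per pixel: the argmax class (1 = gland, 0 = background) when the
#' maximum score reaches `beta_high`; background (0) when it is at most
#' `beta_low`; uncertain (255) otherwise. Both comparisons are closed
#' (>= / <=).
#'
#' @param cam A `class_activation_map` or an h x w x 2 score array in
#'   \[0, 1\] with channel order \[gland, background\].
#' @param beta_low,beta_high Thresholds with `0 < beta_low < beta_high < 1`
#'   (defaults 0.3 and 0.6).
#' @return h x w integer matrix with values in \{0, 1, 255\}.
#' @export
confidence_labels <- function(cam, beta_low = 0.3, beta_high = 0.6) {
  if (beta_low >= beta_high || beta_low <= 0 || beta_high >= 1) {
    stop_maaseg("need 0 < beta_low < beta_high < 1",
                class = "maaseg_config_error")
  }
  scores <- if (inherits(cam, "class_activation_map")) cam$scores else cam
  d <- dim(scores)
  g <- matrix(scores[, , 1L], d[1L], d[2L])
  b <- matrix(scores[, , 2L], d[1L], d[2L])
  mx <- pmax(g, b)
  lab <- matrix(255L, nrow(g), ncol(g))
  lab[mx >= beta_high] <- ifelse(g[mx >= beta_high] >= b[mx >= beta_high], 1L, 0L)
  lab[mx <= beta_low] <- 0L
  lab
}

# Unordered neighbor offsets within Euclidean distance r (half-plane
# representatives so each pair is enumerated once).
radius_offsets <- function(r) {
  offs <- expand.grid(dy = -floor(r):floor(r), dx = 0:floor(r))
  offs <- offs[offs$dx > 0 | (offs$dx == 0 & offs$dy > 0), , drop = FALSE]
  offs[offs$dy^2 + offs$dx^2 <= r^2, , drop = FALSE]
}

#' Positive and negative pixel-pair sets from confidence labels
#'
#' Enumerates all unordered pixel pairs within Euclidean distance `r`;
#' a pair with two identical non-255 labels is positive, with two
#' different non-255 labels negative, and is dropped when either pixel is
#' uncertain (255).
#'
#' @param labels h x w matrix over \{0, 1, 255\}.
#' @param r Neighborhood radius in pixels (default 8).
#' @return List of class `pair_sets`: `pos` and `neg` (two-column
#'   matrices of column-major linear pixel indices), `n_pos`, `n_neg`,
#'   `r`, `dim`.
#' @export
build_pair_sets <- function(labels, r = 8) {
  if (r < 1) stop_maaseg("r must be >= 1", class = "maaseg_config_error")
  h <- nrow(labels); w <- ncol(labels)
  offs <- radius_offsets(r)
  pos <- list(); neg <- list()
  lab <- as.vector(labels)
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    ys <- seq_len(h); xs <- seq_len(w)
    ys <- ys[ys + dy >= 1 & ys + dy <= h]
    xs <- xs[xs + dx >= 1 & xs + dx <= w]
    if (!length(ys) || !length(xs)) next
    i <- rep(ys, times = length(xs)) + (rep(xs, each = length(ys)) - 1L) * h
    j <- i + dy + dx * h
    li <- lab[i]; lj <- lab[j]
    ok <- li != 255L & lj != 255L
    same <- ok & li == lj
    diff <- ok & li != lj
    if (any(same)) pos[[length(pos) + 1L]] <- cbind(i[same], j[same])
    if (any(diff)) neg[[length(neg) + 1L]] <- cbind(i[diff], j[diff])
  }
  pos <- if (length(pos)) do.call(rbind, pos) else matrix(integer(0), 0L, 2L)
  neg <- if (length(neg)) do.call(rbind, neg) else matrix(integer(0), 0L, 2L)
  structure(list(pos = pos, neg = neg, n_pos = nrow(pos), n_neg = nrow(neg),
                 r = r, dim = c(h, w)),
            class = "pair_sets")
}

#' Affinity loss over positive and negative pair scores
#'
#' Mean of `1 - sigmoid(A)` over positive pairs plus mean of `sigmoid(A)`
#' over negative pairs, so that minimizing drives positive-pair
#' affinities up and negative-pair affinities down. An empty set
#' contributes 0; both sets empty is an error.
#'
#' @param scores Numeric vector of pair affinity scores, positives first
#'   (`pairs$n_pos` of them) then negatives.
#' @param pairs A `pair_sets` object giving the pos/neg partition.
#' @return Scalar loss.
#' @export
affinity_loss <- function(scores, pairs) {
  np <- pairs$n_pos; nn <- pairs$n_neg
  if (np + nn == 0L) {
    stop_maaseg("both pair sets empty: affinity loss undefined",
                class = "maaseg_value_error")
  }
  if (length(scores) != np + nn) {
    stop_maaseg("need one score per pair", class = "maaseg_value_error")
  }
  lp <- if (np > 0L) mean(1 - sigmoid(scores[seq_len(np)])) else 0
  ln <- if (nn > 0L) mean(sigmoid(scores[np + seq_len(nn)])) else 0
  lp + ln
}

# ---- affinity head ----------------------------------------------------------

#' Initialize the pixel-pair affinity head
#'
#' A three-layer perceptron over the concatenated descriptors of the two
#' pixels; each pixel's descriptor is its fused multi-level feature vector
#' concatenated with a learned embedding of its initial pseudo-label
#' (0 / 1 / 255). Scores are symmetrized over the two argument orders.
#'
#' @param feature_dim Fused feature channel depth.
#' @param hidden Hidden layer width.
#' @param embed_dim Label embedding dimension.
#' @return List of class `affinity_head`.
#' @export
affinity_head_new <- function(feature_dim, hidden = 64L, embed_dim = 8L) {
  din <- 2L * (feature_dim + embed_dim)
  structure(list(emb = ad_param(matrix(stats::rnorm(3L * embed_dim, sd = 0.5),
                                       3L, embed_dim)),
                 fc1 = new_linear(din, hidden),
                 fc2 = new_linear(hidden, hidden),
                 fc3 = new_linear(hidden, 1L),
                 feature_dim = as.integer(feature_dim),
                 embed_dim = as.integer(embed_dim)),
            class = "affinity_head")
}

label_codes <- function(labels) {
  l <- as.vector(labels)
  ifelse(l == 0, 1L, ifelse(l == 1, 2L, 3L))
}

# leaky rectifier keeps every hidden unit trainable under the saturating
# pairwise loss
leaky <- function(x, alpha = 0.01) pmax(x, alpha * x)

mlp_num <- function(head, X) {
  h1 <- leaky(sweep(X %*% head$fc1$W$value, 2L, as.numeric(head$fc1$b$value), "+"))
  h2 <- leaky(sweep(h1 %*% head$fc2$W$value, 2L, as.numeric(head$fc2$b$value), "+"))
  as.numeric(sweep(h2 %*% head$fc3$W$value, 2L, as.numeric(head$fc3$b$value), "+"))
}

#' Predicted affinity scores for pixel pairs
#'
#' @param head An `affinity_head`.
#' @param features S_h x S_w x C fused feature array (or N x C matrix).
#' @param labels Initial pseudo-labels over \{0, 1, 255\} at the same
#'   resolution.
#' @param pairs Two-column matrix of linear pixel indices.
#' @return Numeric vector of symmetric affinity scores, one per pair.
#' @export
pair_affinity <- function(head, features, labels, pairs) {
  fm <- if (length(dim(features)) == 3L) raster_to_mat(features) else features
  desc <- cbind(fm, head$emb$value[label_codes(labels), , drop = FALSE])
  if (nrow(pairs) == 0L) return(numeric(0))
  d1 <- cbind(desc[pairs[, 1L], , drop = FALSE], desc[pairs[, 2L], , drop = FALSE])
  d2 <- cbind(desc[pairs[, 2L], , drop = FALSE], desc[pairs[, 1L], , drop = FALSE])
  0.5 * (mlp_num(head, d1) + mlp_num(head, d2))
}

# Graph version of the symmetric pair score for training.
pair_affinity_graph <- function(head, feat_node, codes, pairs) {
  desc <- ad_cbind(list(feat_node, ad_rows(head$emb, codes)))
  d1 <- ad_cbind(list(ad_rows(desc, pairs[, 1L]), ad_rows(desc, pairs[, 2L])))
  d2 <- ad_cbind(list(ad_rows(desc, pairs[, 2L]), ad_rows(desc, pairs[, 1L])))
  mlp <- function(X) {
    h1 <- ad_leaky_relu(ad_add_bias(ad_matmul(X, head$fc1$W), head$fc1$b))
    h2 <- ad_leaky_relu(ad_add_bias(ad_matmul(h1, head$fc2$W), head$fc2$b))
    ad_add_bias(ad_matmul(h2, head$fc3$W), head$fc3$b)
  }
  ad_scale(ad_add(mlp(d1), mlp(d2)), 0.5)
}

affinity_stage_defaults <- function() {
  list(r = 8, beta_low = 0.3, beta_high = 0.6, hidden = 64L, embed_dim = 8L,
       epochs = 30L, lr = 0.01, momentum = 0.5, max_pairs = 1500L,
       refine_scale = 4L, label_dropout = 0.5, seed = 0L, verbose = FALSE)
}

# Refinement works on a grid `refine_scale` times finer than the CAM
# (1/4 of patch resolution by default), where the radius-r neighborhood
# is genuinely local; features and scores are upsampled bilinearly.
refine_res <- function(cam, scale) {
  d <- dim(cam$scores)
  c(d[1L] * scale, d[2L] * scale)
}

# Class-presence gating: a channel whose image-level class is predicted
# absent is zeroed before thresholding, and when only one class is
# predicted present every pixel belongs to it with full confidence.
# Per-patch min-max normalization is only meaningful when both classes
# actually occur in the patch; on a single-class patch it stretches
# within-class noise across [0, 1].
gated_scores <- function(cam) {
  sc <- cam$scores
  bits <- sigmoid(as.numeric(cam$logits)) > 0.5
  if (xor(bits[1L], bits[2L])) {
    sc[, , which(bits)] <- 1
    sc[, , which(!bits)] <- 0
  }
  sc
}

upsample_cam_case <- function(cam, scale, beta_low, beta_high) {
  rr <- refine_res(cam, scale)
  feat <- bilinear_resize(cam$fused, rr[1L], rr[2L])
  cam$scores <- gated_scores(cam)
  # per-patch channel standardization conditions the affinity head's SGD
  m <- raster_to_mat(feat)
  m <- sweep(m, 2L, colMeans(m), "-")
  m <- sweep(m, 2L, pmax(apply(m, 2L, stats::sd), 1e-6), "/")
  feat <- mat_to_raster(m, rr[1L], rr[2L])
  sc <- clamp(bilinear_resize(cam$scores, rr[1L], rr[2L]), 0, 1)
  lab <- confidence_labels(sc, beta_low, beta_high)
  list(feat = feat, scores = sc, labels = lab, rh = rr[1L], rw = rr[2L])
}

#' Train the affinity head on confidence-label pair supervision
#'
#' For every training patch, the initial CAM yields confidence labels
#' (at CAM resolution); pixel pairs within radius `r` supervise the MLP
#' through the affinity loss. Fused features are treated as fixed inputs;
#' only the MLP and the label embedding are optimized (SGD).
#'
#' @param cams List of `class_activation_map` objects (with `fused`
#'   features), one per training patch.
#' @param config Named list overriding `affinity_stage_defaults()`.
#' @param images Optional list of the corresponding RGB patches (0-255
#'   arrays). When given, the pair supervision is built from
#'   pixel-adaptive-refined scores (initial pseudo-labels combined with
#'   local RGB consistency), so negative pairs concentrate on true
#'   appearance boundaries; the descriptor embeddings still encode the
#'   raw initial labels.
#' @return List with `head` (trained `affinity_head`) and `log`.
#' @export
train_affinity_stage <- function(cams, config = list(), images = NULL) {
  cfg <- utils::modifyList(affinity_stage_defaults(), config)
  if (!length(cams)) stop_maaseg("no CAMs provided", class = "maaseg_value_error")
  if (!is.null(images) && length(images) != length(cams)) {
    stop_maaseg("need one image per CAM", class = "maaseg_value_error")
  }
  set.seed(cfg$seed)
  feature_dim <- dim(cams[[1L]]$fused)[3L]
  head <- affinity_head_new(feature_dim, cfg$hidden, cfg$embed_dim)
  params <- collect_params(head)
  cases <- lapply(seq_along(cams), function(k) {
    cam <- cams[[k]]
    up <- upsample_cam_case(cam, cfg$refine_scale, cfg$beta_low, cfg$beta_high)
    pair_labels <- up$labels
    if (!is.null(images)) {
      img <- images[[k]]
      H <- dim(img)[1L]; W <- dim(img)[2L]
      full <- clamp(bilinear_resize(gated_scores(cam), H, W), 0, 1)
      par_full <- par_refine(img, full, iterations = cfg$par_iters %||% 10L)
      pooled <- mat_to_raster(as.matrix(pool_matrix(H, W, up$rh, up$rw) %*%
                                          raster_to_mat(par_full)),
                              up$rh, up$rw)
      pair_labels <- confidence_labels(clamp(pooled, 0, 1),
                                       cfg$beta_low, cfg$beta_high)
    }
    ps <- build_pair_sets(pair_labels, cfg$r)
    list(feat = raster_to_mat(up$feat), codes = label_codes(up$labels),
         ps = ps)
  })
  cases <- Filter(function(cs) cs$ps$n_pos + cs$ps$n_neg > 0L, cases)
  if (!length(cases)) {
    stop_maaseg("no labeled pixel pairs in any patch",
                class = "maaseg_value_error")
  }
  log <- data.frame(epoch = integer(0), loss = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    total <- 0
    for (cs in cases) {
      ps <- cs$ps
      pos <- ps$pos; neg <- ps$neg
      if (nrow(pos) > cfg$max_pairs) {
        pos <- pos[sample.int(nrow(pos), cfg$max_pairs), , drop = FALSE]
      }
      if (nrow(neg) > cfg$max_pairs) {
        neg <- neg[sample.int(nrow(neg), cfg$max_pairs), , drop = FALSE]
      }
      pairs <- rbind(pos, neg)
      if (!nrow(pairs)) next
      zero_grads(params)
      codes <- cs$codes
      if (cfg$label_dropout > 0) {
        # randomly mask label codes to "uncertain" so the head cannot rely
        # on the label-equality shortcut alone and must use the features;
        # also trains the uncertain-label embedding seen at inference
        drop <- stats::runif(length(codes)) < cfg$label_dropout
        codes[drop] <- 3L
      }
      s <- pair_affinity_graph(head, ad_node(cs$feat), codes, pairs)
      sg <- ad_sigmoid(s)
      terms <- list()
      if (nrow(pos) > 0L) {
        terms <- c(terms, list(
          ad_scale(ad_sum(ad_mul_const(ad_rows(sg, seq_len(nrow(pos))), -1)),
                   1 / nrow(pos))))
      }
      if (nrow(neg) > 0L) {
        terms <- c(terms, list(
          ad_scale(ad_sum(ad_rows(sg, nrow(pos) + seq_len(nrow(neg)))),
                   1 / nrow(neg))))
      }
      loss <- ad_add_list(terms)
      ad_backward(loss)
      sgd_step(params, cfg$lr, cfg$momentum, clip_norm = 5)
      # report the bounded form (constant offset restores the mean(1-s) term)
      total <- total + loss$value + (nrow(pos) > 0L)
    }
    log <- rbind(log, data.frame(epoch = epoch, loss = total / length(cases)))
    if (isTRUE(cfg$verbose)) {
      message(sprintf("affinity epoch %d/%d loss %.4f", epoch, cfg$epochs,
                      log$loss[nrow(log)]))
    }
  }
  list(head = head, log = log)
}

# ---- PAR and random walk ----------------------------------------------------

# Row-stochastic PAR smoothing operator from RGB and positional kernels:
# softmax over (self + 8 neighbors at each dilation) of
# -||rgb_i - rgb_j||^2 / (2 s_rgb^2) - ||p_i - p_j||^2 / (2 s_pos^2).
par_operator <- function(image01, dilations, sigma_rgb, sigma_pos) {
  h <- dim(image01)[1L]; w <- dim(image01)[2L]
  n <- h * w
  rgb <- raster_to_mat(image01)
  offs <- list(c(0L, 0L))
  for (d in dilations) {
    for (dx in c(-d, 0L, d)) for (dy in c(-d, 0L, d)) {
      if (dx != 0L || dy != 0L) offs[[length(offs) + 1L]] <- c(dy, dx)
    }
  }
  K <- length(offs)
  E <- matrix(-Inf, n, K)
  tgt <- matrix(1L, n, K)
  yy <- rep(seq_len(h), times = w)
  xx <- rep(seq_len(w), each = h)
  for (k in seq_len(K)) {
    dy <- offs[[k]][1L]; dx <- offs[[k]][2L]
    ok <- yy + dy >= 1L & yy + dy <= h & xx + dx >= 1L & xx + dx <= w
    j <- (yy + dy) + (xx + dx - 1L) * h
    j[!ok] <- 1L
    dd <- rgb - rgb[j, , drop = FALSE]
    e <- -rowSums(dd * dd) / (2 * sigma_rgb^2) -
      (dy^2 + dx^2) / (2 * sigma_pos^2)
    e[!ok] <- -Inf
    E[, k] <- e
    tgt[, k] <- j
  }
  E <- E - apply(E, 1L, max)
  W <- exp(E)
  W[!is.finite(W)] <- 0
  W <- W / rowSums(W)
  keep <- as.vector(W) > 0
  Matrix::sparseMatrix(i = rep(seq_len(n), times = K)[keep],
                       j = as.vector(tgt)[keep],
                       x = as.vector(W)[keep], dims = c(n, n))
}

#' Pixel-adaptive refinement of score maps
#'
#' Iteratively replaces each pixel's score by a convex combination of its
#' own and its neighbors' scores, weighted by a softmax over negated RGB
#' and spatial distance kernels (8-neighborhoods at the given dilations).
#' Preserves the score range per class.
#'
#' @param image H x W x 3 array on the 0-255 scale (the RGB guidance).
#' @param scores H x W x K score array aligned with the image.
#' @param iterations Number of smoothing passes (default 10).
#' @param dilations Neighborhood dilation radii (default 1, 2, 4, 8).
#' @param sigma_rgb RGB kernel bandwidth on 0-1 intensities (default 0.1).
#' @param sigma_pos Spatial kernel bandwidth in pixels (default 6).
#' @return Refined H x W x K score array.
#' @export
par_refine <- function(image, scores, iterations = 10L,
                       dilations = c(1L, 2L, 4L, 8L),
                       sigma_rgb = 0.1, sigma_pos = 6) {
  d <- dim(scores)
  if (!identical(dim(image)[1:2], d[1:2])) {
    stop_maaseg("image and scores must be spatially aligned",
                class = "maaseg_dimension_error")
  }
  W <- par_operator(image / 255, dilations, sigma_rgb, sigma_pos)
  s <- raster_to_mat(scores)
  for (it in seq_len(iterations)) s <- as.matrix(W %*% s)
  mat_to_raster(s, d[1L], d[2L])
}

#' Build the sparse affinity matrix on the radius-r support
#'
#' Evaluates the trained affinity head on every in-radius pixel pair and
#' maps scores through the sigmoid; the result is symmetric, non-negative
#' and zero off the support.
#'
#' @param head Trained `affinity_head`.
#' @param features Fused feature array (S_h x S_w x C).
#' @param labels Initial pseudo-labels at the same resolution.
#' @param r Support radius (default 8).
#' @return Sparse symmetric N x N matrix (N = S_h * S_w).
#' @export
affinity_matrix <- function(head, features, labels, r = 8) {
  h <- dim(features)[1L]; w <- dim(features)[2L]
  offs <- radius_offsets(r)
  pairs <- list()
  for (k in seq_len(nrow(offs))) {
    dy <- offs$dy[k]; dx <- offs$dx[k]
    ys <- seq_len(h); xs <- seq_len(w)
    ys <- ys[ys + dy >= 1 & ys + dy <= h]
    xs <- xs[xs + dx >= 1 & xs + dx <= w]
    if (!length(ys) || !length(xs)) next
    i <- rep(ys, times = length(xs)) + (rep(xs, each = length(ys)) - 1L) * h
    pairs[[length(pairs) + 1L]] <- cbind(i, i + dy + dx * h)
  }
  pairs <- do.call(rbind, pairs)
  a <- sigmoid(pair_affinity(head, features, labels, pairs))
  n <- h * w
  Matrix::sparseMatrix(i = c(pairs[, 1L], pairs[, 2L]),
                       j = c(pairs[, 2L], pairs[, 1L]),
                       x = c(a, a), dims = c(n, n))
}

#' Random-walk propagation of class scores
#'
#' Builds the transition operator `T = rownorm(A^∘beta + I)` (Hadamard
#' power of the affinity matrix plus unit self-loops, rows normalized to
#' sum to one) and applies it `t` times to each class-score channel.
#' Output is clipped to \[0, 1\].
#'
#' @param cam S_h x S_w x K score array (or a `class_activation_map`).
#' @param affinity_map Sparse non-negative N x N affinity matrix on the
#'   local support, as from [affinity_matrix()].
#' @param beta Hadamard power sharpening the affinities (default 8).
#' @param t Number of propagation steps (default 4).
#' @return Refined score array of the same shape.
#' @export
random_walk <- function(cam, affinity_map, beta = 8, t = 4L) {
  scores <- if (inherits(cam, "class_activation_map")) cam$scores else cam
  d <- dim(scores)
  n <- d[1L] * d[2L]
  A <- methods::as(affinity_map, "CsparseMatrix")
  if (any(A@x < 0)) {
    stop_maaseg("affinities must be non-negative", class = "maaseg_value_error")
  }
  A@x <- A@x^beta
  rs <- Matrix::rowSums(A) + 1
  Tm <- Matrix::Diagonal(x = 1 / rs) %*% (A + Matrix::Diagonal(n))
  s <- raster_to_mat(scores)
  for (it in seq_len(t)) s <- as.matrix(Tm %*% s)
  mat_to_raster(clamp(s, 0, 1), d[1L], d[2L])
}

#' Threshold refined scores into final pseudo-labels
#'
#' Re-applies the confidence thresholding to refined scores, optionally
#' after bilinear upsampling to the patch resolution.
#'
#' @param refined S_h x S_w x 2 refined score array in \[0, 1\].
#' @param beta_low,beta_high Confidence thresholds.
#' @param out_size Optional `c(height, width)` to upsample to before
#'   thresholding.
#' @return Integer matrix over \{0, 1, 255\}.
#' @export
finalize_pseudo_labels <- function(refined, beta_low = 0.3, beta_high = 0.6,
                                   out_size = NULL) {
  if (!is.null(out_size)) {
    refined <- clamp(bilinear_resize(refined, out_size[1L], out_size[2L]), 0, 1)
  }
  confidence_labels(refined, beta_low, beta_high)
}

#' Full pseudo-label refinement for one patch
#'
#' The two-step refinement: pixel-adaptive smoothing of the upsampled CAM
#' under the patch RGB, then random-walk propagation at CAM resolution
#' through the learned affinities, followed by confidence thresholding at
#' patch resolution.
#'
#' @param cam `class_activation_map` for the patch (with fused features).
#' @param image The patch (H x W x 3, 0-255).
#' @param head Trained `affinity_head`.
#' @param config Named list overriding `affinity_stage_defaults()` plus
#'   `beta_power` (random-walk Hadamard power, default 8), `walk_iters`
#'   (default 4), `par_iters` (default 10).
#' @return List with `pseudo` (H x W labels over \{0,1,255\}),
#'   `raw` (labels from the unrefined CAM at the same resolution) and
#'   `refined_scores`.
#' @export
refine_pseudo_label <- function(cam, image, head, config = list()) {
  cfg <- utils::modifyList(c(affinity_stage_defaults(),
                             list(beta_power = 8, walk_iters = 4L,
                                  par_iters = 10L)),
                           config)
  H <- dim(image)[1L]; W <- dim(image)[2L]
  full <- clamp(bilinear_resize(gated_scores(cam), H, W), 0, 1)
  raw <- confidence_labels(full, cfg$beta_low, cfg$beta_high)
  up <- upsample_cam_case(cam, cfg$refine_scale, cfg$beta_low, cfg$beta_high)
  smoothed <- par_refine(image, full, iterations = cfg$par_iters)
  pooled <- mat_to_raster(as.matrix(pool_matrix(H, W, up$rh, up$rw) %*%
                                      raster_to_mat(smoothed)), up$rh, up$rw)
  A <- affinity_matrix(head, up$feat, up$labels, cfg$r)
  walked <- random_walk(pooled, A, beta = cfg$beta_power, t = cfg$walk_iters)
  pseudo <- finalize_pseudo_labels(walked, cfg$beta_low, cfg$beta_high,
                                   out_size = c(H, W))
  list(pseudo = pseudo, raw = raw,
       refined_scores = clamp(bilinear_resize(walked, H, W), 0, 1))
}
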