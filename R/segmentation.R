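# Segmentation stage: a small pyramid-pooling segmentation network
# trained on pseudo-labels with the online easy-example-mining (OEEM)
# normalized loss. Logit channel order is [background, gland] so channel
# index = class label + 1; pixels labeled 255 are ignored everywhere.

seg_stage_defaults <- function() {
  list(channels = c(16L, 32L), ppm_dim = 8L, ppm_bins = c(1L, 2L, 3L, 6L),
       iterations = 10000L, batch_size = 32L, lr = 5e-4, momentum = 0.9,
       weight_decay = 1e-4, oeem = TRUE, oeem_scope = c("image", "batch"),
       augment = TRUE, flip_prob = 0.5, seed = 0L, verbose = FALSE,
       log_every = 50L)
}

#' Initialize the segmentation network
#'
#' A compact residual CNN with a pyramid pooling module: strided stem and
#' one downsampling stage (overall 1/4 resolution), a residual block at
#' each scale, adaptive-average-pool pyramid branches at bins
#' \{1, 2, 3, 6\} concatenated with the backbone features, a 3x3 fusion
#' convolution and a 1x1 two-class classifier, bilinearly upsampled to
#' input resolution.
#'
#' @param channels Backbone channel depths (two stages).
#' @param ppm_dim Channels of each pyramid branch.
#' @param ppm_bins Pyramid pooling bin sizes.
#' @return List of class `psp_model`.
#' @export
psp_new <- function(channels = c(16L, 32L), ppm_dim = 8L,
                    ppm_bins = c(1L, 2L, 3L, 6L)) {
  c1 <- channels[1L]; c2 <- channels[2L]
  structure(list(
    stem = new_conv(3L, c1, 3L),
    res1 = list(a = new_conv(c1, c1, 3L), b = new_conv(c1, c1, 3L)),
    down = new_conv(c1, c2, 3L),
    res2 = list(a = new_conv(c2, c2, 3L), b = new_conv(c2, c2, 3L)),
    ppm = lapply(ppm_bins, function(b) new_linear(c2, ppm_dim)),
    fusec = new_conv(c2 + length(ppm_bins) * ppm_dim, c2, 3L),
    cls = new_linear(c2, 2L),
    channels = as.integer(channels), ppm_dim = as.integer(ppm_dim),
    ppm_bins = as.integer(ppm_bins), norm = NULL),
    class = "psp_model")
}

res_block_forward <- function(x, blk, h, w) {
  z <- ad_relu(ad_conv2d(x, blk$a$W, blk$a$b, h, w, 3L, 1L))
  z <- ad_conv2d(z, blk$b$W, blk$b$b, h, w, 3L, 1L)
  out <- ad_relu(ad_add(x, z))
  out$h <- h; out$w <- w
  out
}

psp_forward_graph <- function(model, x, h, w) {
  z <- ad_relu(ad_conv2d(x, model$stem$W, model$stem$b, h, w, 3L, 2L))
  h1 <- as.integer(ceiling(h / 2)); w1 <- as.integer(ceiling(w / 2))
  z <- res_block_forward(z, model$res1, h1, w1)
  z <- ad_relu(ad_conv2d(z, model$down$W, model$down$b, h1, w1, 3L, 2L))
  h2 <- as.integer(ceiling(h1 / 2)); w2 <- as.integer(ceiling(w1 / 2))
  z <- res_block_forward(z, model$res2, h2, w2)
  branches <- list(z)
  for (k in seq_along(model$ppm_bins)) {
    b <- model$ppm_bins[k]
    bh <- min(b, h2); bw <- min(b, w2)
    p <- ad_spmm(pool_matrix(h2, w2, bh, bw), z)
    p <- ad_relu(ad_add_bias(ad_matmul(p, model$ppm[[k]]$W), model$ppm[[k]]$b))
    branches[[k + 1L]] <- ad_spmm(bilinear_matrix(bh, bw, h2, w2), p)
  }
  z <- ad_cbind(branches)
  z <- ad_relu(ad_conv2d(z, model$fusec$W, model$fusec$b, h2, w2, 3L, 1L))
  logits <- ad_add_bias(ad_matmul(z, model$cls$W), model$cls$b)
  out <- ad_spmm(bilinear_matrix(h2, w2, h, w), logits)
  out$h <- h; out$w <- w
  out
}

#' Forward pass of the segmentation network
#'
#' @param model A `psp_model`.
#' @param image H x W x 3 array on the 0-255 scale.
#' @return H x W x 2 logit array, channel order \[background, gland\].
#' @export
psp_forward <- function(model, image) {
  d <- dim(image)
  x <- ad_node(normalize_image(model, image))
  out <- psp_forward_graph(model, x, d[1L], d[2L])
  mat_to_raster(out$value, d[1L], d[2L])
}

#' Per-pixel cross-entropy under a pseudo-label mask
#'
#' `-log softmax` at the labeled class for every valid (non-255) pixel;
#' ignored pixels are `NA`.
#'
#' @param logits H x W x C logit array (C = 2, \[background, gland\]).
#' @param mask H x W pseudo-labels over \{0, 1, 255\}.
#' @return H x W matrix of losses with `NA` at ignored pixels.
#' @export
pixel_ce <- function(logits, mask) {
  d <- dim(logits)
  if (!identical(d[1:2], dim(mask)[1:2])) {
    stop_maaseg("mask and logits must be aligned", class = "maaseg_dimension_error")
  }
  lab <- as.vector(mask)
  valid <- lab != 255
  if (!any(valid)) {
    stop_maaseg("all pixels ignored: loss undefined",
                class = "maaseg_value_error")
  }
  z <- raster_to_mat(logits)
  z <- z - row_max(z)
  p <- exp(z)
  p <- p / rowSums(p)
  out <- rep(NA_real_, length(lab))
  pick <- cbind(which(valid), lab[valid] + 1L)
  out[valid] <- -log(pmax(p[pick], 1e-300))
  matrix(out, d[1L], d[2L])
}

#' Online easy-example-mining weights from a loss map
#'
#' `w = softmax(-L) / mean(softmax(-L))` over the valid pixels of one
#' image: low-loss (reliable) pixels get weight above 1. Losses are
#' clamped at 50 before the softmax for numerical stability. The weights
#' average exactly to 1.
#'
#' @param loss_map Matrix of per-pixel losses with `NA` at ignored pixels
#'   (from [pixel_ce()]), or a numeric vector.
#' @return Object of the same shape with weights at valid pixels and `NA`
#'   elsewhere.
#' @export
oeem_weights <- function(loss_map) {
  l <- as.vector(loss_map)
  valid <- !is.na(l)
  if (!any(valid)) {
    stop_maaseg("no valid pixels", class = "maaseg_value_error")
  }
  z <- -pmin(l[valid], 50)
  z <- z - max(z)
  s <- exp(z)
  s <- s / sum(s)
  w <- s / mean(s)
  out <- rep(NA_real_, length(l))
  out[valid] <- w
  if (is.matrix(loss_map)) matrix(out, nrow(loss_map), ncol(loss_map)) else out
}

#' Normalized segmentation loss (OEEM)
#'
#' With more than one distinct class among the valid pixels, returns the
#' OEEM-weighted mean of the per-pixel cross-entropies (weights treated
#' as constants); with a single class, the plain mean cross-entropy.
#'
#' @inheritParams pixel_ce
#' @return Scalar loss.
#' @export
normalized_loss <- function(logits, mask) {
  lm <- pixel_ce(logits, mask)
  l <- as.vector(lm)
  valid <- !is.na(l)
  n_classes <- length(unique(as.vector(mask)[valid]))
  if (n_classes > 1L) {
    w <- as.vector(oeem_weights(lm))
    mean(w[valid] * l[valid])
  } else {
    mean(l[valid])
  }
}

read_pseudo <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  v <- round(a * 255)
  out <- matrix(255L, nrow(a), ncol(a))
  out[v == 0] <- 0L
  out[v == 128] <- 1L
  out
}

#' Write a pseudo-label mask PNG
#'
#' Palette: class 0 -> 0, class 1 (gland) -> 128, uncertain 255 -> 255.
#' @param pseudo H x W matrix over \{0, 1, 255\}.
#' @param path Output path.
#' @export
write_pseudo <- function(pseudo, path) {
  v <- matrix(255, nrow(pseudo), ncol(pseudo))
  v[pseudo == 0] <- 0
  v[pseudo == 1] <- 128
  png::writePNG(v / 255, path)
}

#' Train the segmentation stage on pseudo-labels
#'
#' SGD at a fixed learning rate (defaults: lr 5e-4, batch 32, 10000
#' iterations; scale down via `config` for desk runs) minimizing the
#' normalized OEEM loss. OEEM weighting is computed per image by default
#' (`oeem_scope = "batch"` pools the softmax over the whole batch).
#'
#' @param pseudo_manifest Data frame with columns `image_path` and
#'   `pseudo_path` (pseudo-label PNGs as written by [write_pseudo()]).
#' @param config Named list overriding `seg_stage_defaults()`.
#' @return List with `model` (trained `psp_model`) and `log` (data frame
#'   of iteration and loss).
#' @export
train_seg_stage <- function(pseudo_manifest, config = list()) {
  cfg <- utils::modifyList(seg_stage_defaults(), config)
  cfg$oeem_scope <- match.arg(cfg$oeem_scope, c("image", "batch"))
  if (is.null(pseudo_manifest) || nrow(pseudo_manifest) == 0L) {
    stop_maaseg("empty pseudo-label manifest", class = "maaseg_value_error")
  }
  set.seed(cfg$seed)
  imgs <- lapply(pseudo_manifest$image_path, function(p) read_image(p) / 255)
  labs <- lapply(pseudo_manifest$pseudo_path, read_pseudo)
  keep <- vapply(labs, function(l) any(l != 255L), logical(1))
  if (!any(keep)) {
    stop_maaseg("no patch has any valid pseudo-label pixel",
                class = "maaseg_value_error")
  }
  imgs <- imgs[keep]; labs <- labs[keep]
  px <- do.call(rbind, lapply(imgs, raster_to_mat))
  norm <- list(mean = colMeans(px), sd = pmax(apply(px, 2L, stats::sd), 1e-3))
  model <- psp_new(cfg$channels, cfg$ppm_dim, cfg$ppm_bins)
  model$norm <- norm
  params <- collect_params(model[c("stem", "res1", "down", "res2", "ppm",
                                   "fusec", "cls")])
  n <- length(imgs)
  log <- data.frame(iteration = integer(0), loss = numeric(0))
  for (iter in seq_len(cfg$iterations)) {
    ids <- sample.int(n, min(cfg$batch_size, n), replace = cfg$batch_size > n)
    zero_grads(params)
    ce_nodes <- vector("list", length(ids))
    ce_meta <- vector("list", length(ids))
    for (j in seq_along(ids)) {
      img <- imgs[[ids[j]]]
      lab <- labs[[ids[j]]]
      if (cfg$augment) {
        if (stats::runif(1) < cfg$flip_prob) {
          img <- img[rev(seq_len(dim(img)[1L])), , , drop = FALSE]
          lab <- lab[rev(seq_len(nrow(lab))), , drop = FALSE]
        }
        if (stats::runif(1) < cfg$flip_prob) {
          img <- img[, rev(seq_len(dim(img)[2L])), , drop = FALSE]
          lab <- lab[, rev(seq_len(ncol(lab))), drop = FALSE]
        }
      }
      h <- nrow(lab); w <- ncol(lab)
      m <- sweep(sweep(raster_to_mat(img), 2L, norm$mean, "-"), 2L, norm$sd, "/")
      out <- psp_forward_graph(model, ad_node(m), h, w)
      lv <- as.vector(lab)
      valid <- which(lv != 255L)
      ce_nodes[[j]] <- ad_ce_vector(out, lv[valid] + 1L, valid)
      ce_meta[[j]] <- list(classes = length(unique(lv[valid])),
                           n_valid = length(valid))
    }
    loss_terms <- vector("list", length(ids))
    if (cfg$oeem_scope == "batch" &&
        any(vapply(ce_meta, function(m) m$classes, 0L) > 1L)) {
      all_l <- unlist(lapply(ce_nodes, function(nd) as.numeric(nd$value)))
      w_all <- oeem_weights(all_l)
      at <- 0L
      for (j in seq_along(ids)) {
        nv <- ce_meta[[j]]$n_valid
        loss_terms[[j]] <- ad_dot_const(ce_nodes[[j]],
                                        w_all[at + seq_len(nv)] / length(all_l))
        at <- at + nv
      }
    } else {
      for (j in seq_along(ids)) {
        nv <- ce_meta[[j]]$n_valid
        w <- if (cfg$oeem && ce_meta[[j]]$classes > 1L) {
          oeem_weights(as.numeric(ce_nodes[[j]]$value))
        } else rep(1, nv)
        loss_terms[[j]] <- ad_dot_const(ce_nodes[[j]], w / (nv * length(ids)))
      }
    }
    loss <- ad_add_list(loss_terms)
    ad_backward(loss)
    sgd_step(params, cfg$lr, cfg$momentum, cfg$weight_decay)
    if (iter == 1L || iter %% cfg$log_every == 0L || iter == cfg$iterations) {
      log <- rbind(log, data.frame(iteration = iter, loss = loss$value))
      if (isTRUE(cfg$verbose)) {
        message(sprintf("seg iter %d/%d loss %.4f", iter, cfg$iterations,
                        loss$value))
      }
    }
  }
  list(model = model, log = log)
}

# Per-pixel CE over the valid pixels as one graph node (column vector).
ad_ce_vector <- function(logits, lab_idx, valid) {
  z <- logits$value[valid, , drop = FALSE]
  z <- z - row_max(z)
  p <- exp(z)
  p <- p / rowSums(p)
  pick <- cbind(seq_along(valid), lab_idx)
  out <- ad_node(matrix(-log(pmax(p[pick], 1e-300)), ncol = 1L), list(logits))
  out$backward <- function(n) {
    g <- as.numeric(n$grad)
    G <- p * g
    G[pick] <- G[pick] - g
    full <- matrix(0, nrow(logits$value), ncol(logits$value))
    full[valid, ] <- G
    ad_accum(logits, full)
  }
  out
}

#' Predict a binary gland mask for an image
#'
#' @param model Trained `psp_model`.
#' @param image H x W x 3 array (0-255).
#' @return H x W integer matrix (1 = gland).
#' @export
segment_image <- function(model, image) {
  logits <- psp_forward(model, image)
  (logits[, , 2L] > logits[, , 1L]) * 1L
}
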