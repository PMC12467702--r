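# Multi-level attention fusion: align encoder features from layers
# {3, 5, 6} to a common resolution, sum them, and train a classifier head
# under image-level [gland, background] supervision. The classifier-head
# response before pooling, rectified and min-max normalized, is the class
# activation map used as the initial pseudo-label.

cam_stage_defaults <- function() {
  list(encoder = encoder_config("tiny"),
       fuse_layers = c(3L, 5L, 6L),
       common_dim = 32L,
       epochs = 200L, batch_size = 16L,
       lr = 0.002, min_lr = 0, momentum = 0.9, weight_decay = 1e-4,
       augment = TRUE, flip_prob = 0.5, crop_ratio = c(0.7, 1.0),
       seed = 0L, verbose = FALSE)
}

#' Initialize an untrained CAM model
#'
#' @param encoder An [encoder_config()].
#' @param fuse_layers Encoder layers whose features are fused (default
#'   `c(3, 5, 6)`: coarse localization, structural completeness, boundary
#'   refinement).
#' @param common_dim Channel depth after the per-layer 1x1 projections.
#' @return A list of class `maf_model` (encoder, projections, classifier
#'   head, normalization statistics).
#' @export
maf_new <- function(encoder = encoder_config("tiny"),
                    fuse_layers = c(3L, 5L, 6L), common_dim = 32L) {
  enc <- encoder_new(encoder)
  proj <- lapply(fuse_layers, function(i) {
    new_linear(encoder$channels[i], common_dim)
  })
  names(proj) <- paste0("L", fuse_layers)
  # zero-initialized head: the first update aligns it with the correlation
  # between fused features and the label bits, removing the run-to-run
  # lottery of a random initial class direction
  head <- list(W = ad_param(matrix(0, common_dim, 2L)),
               b = ad_param(numeric(2L)))
  structure(list(encoder = enc, proj = proj, head = head,
                 fuse_layers = as.integer(fuse_layers),
                 common_dim = as.integer(common_dim),
                 norm = NULL),
            class = "maf_model")
}

# Graph forward: returns score raster node (N_S x 2), pooled logits node
# and the target resolution. Target resolution S is the finest fused
# layer's resolution.
maf_forward <- function(model, x, h, w) {
  pyr <- encoder_forward(model$encoder, x, h, w)
  tgt <- pyr[[min(model$fuse_layers)]]
  Sh <- tgt$h; Sw <- tgt$w
  fused <- NULL
  for (k in seq_along(model$fuse_layers)) {
    i <- model$fuse_layers[k]
    Fi <- pyr[[i]]
    up <- if (Fi$h == Sh && Fi$w == Sw) Fi else {
      ad_spmm(bilinear_matrix(Fi$h, Fi$w, Sh, Sw), Fi)
    }
    al <- ad_add_bias(ad_matmul(up, model$proj[[k]]$W), model$proj[[k]]$b)
    fused <- if (is.null(fused)) al else ad_add(fused, al)
  }
  score <- ad_add_bias(ad_matmul(fused, model$head$W), model$head$b)
  logits <- ad_colmeans(score)
  list(score = score, logits = logits, fused = fused, Sh = Sh, Sw = Sw,
       pyramid = pyr)
}

#' Align one pyramid feature map to a target resolution
#'
#' Bilinear upsampling to `S` followed by a learned 1x1 channel
#' projection.
#'
#' @param Fi h x w x C numeric array (a pyramid level).
#' @param S Target spatial size `c(height, width)`.
#' @param weights Optional `list(W, b)` projection (C x C' matrix and
#'   length-C' bias); defaults to the identity projection.
#' @return S\[1\] x S\[2\] x C' array.
#' @export
align_feature <- function(Fi, S, weights = NULL) {
  d <- dim(Fi)
  if (is.null(weights)) {
    weights <- list(W = diag(d[3L]), b = numeric(d[3L]))
  }
  m <- raster_to_mat(Fi)
  if (!(d[1L] == S[1L] && d[2L] == S[2L])) {
    m <- as.matrix(bilinear_matrix(d[1L], d[2L], S[1L], S[2L]) %*% m)
  }
  out <- sweep(m %*% weights$W, 2L, as.numeric(weights$b), "+")
  mat_to_raster(out, S[1L], S[2L])
}

#' Fuse aligned feature maps by element-wise summation
#'
#' @param ... Two or more arrays of identical shape.
#' @return Array of the same shape holding the element-wise sum.
#' @export
fuse <- function(...) {
  maps <- list(...)
  d <- dim(maps[[1L]])
  for (m in maps[-1L]) {
    if (!identical(dim(m), d)) {
      stop_maaseg("fused maps must share a shape", class = "maaseg_dimension_error")
    }
  }
  Reduce(`+`, maps)
}

#' Class logits from a fused feature map
#'
#' Applies the 1x1 classifier head to every position and global-average
#' pools the per-class score raster into a 2-vector of logits.
#'
#' @param model A `maf_model`.
#' @param Fmulti S_h x S_w x common_dim array.
#' @return Named numeric vector `c(gland =, background =)`.
#' @export
classify <- function(model, Fmulti) {
  m <- raster_to_mat(Fmulti)
  score <- sweep(m %*% model$head$W$value, 2L, as.numeric(model$head$b$value), "+")
  stats::setNames(colMeans(score), c("gland", "background"))
}

# ---- augmentation -----------------------------------------------------------

# Random crop (area-preserving resize back) + random flips on a 0-1 image.
augment_image <- function(img01, flip_prob, crop_ratio) {
  d <- dim(img01)
  ratio <- stats::runif(1, crop_ratio[1L], crop_ratio[2L])
  ch <- max(8L, round(d[1L] * ratio))
  cw <- max(8L, round(d[2L] * ratio))
  oy <- sample.int(d[1L] - ch + 1L, 1L) - 1L
  ox <- sample.int(d[2L] - cw + 1L, 1L) - 1L
  img01 <- img01[oy + seq_len(ch), ox + seq_len(cw), , drop = FALSE]
  if (ch != d[1L] || cw != d[2L]) {
    img01 <- clamp(bilinear_resize(img01, d[1L], d[2L]), 0, 1)
  }
  if (stats::runif(1) < flip_prob) img01 <- img01[rev(seq_len(d[1L])), , , drop = FALSE]
  if (stats::runif(1) < flip_prob) img01 <- img01[, rev(seq_len(d[2L])), , drop = FALSE]
  img01
}

# ---- training ---------------------------------------------------------------

#' Train the CAM stage under image-level supervision
#'
#' Optimizes per-class binary cross-entropy on the pooled logits with SGD
#' and cosine-annealed learning rate (defaults: lr 0.002 decaying to 0,
#' batch 16, 200 epochs). Augmentation: random horizontal/vertical flips
#' (p = 0.5 each), random crops with ratio 0.7-1.0 resized back, and
#' per-channel normalization with dataset statistics.
#'
#' @param patch_manifest Data frame with columns `image_path`,
#'   `gland_bit`, `background_bit` (as written by [tile_dataset()]).
#' @param config Named list overriding the defaults above; notable keys:
#'   `epochs`, `batch_size`, `lr`, `seed`, `encoder` (an
#'   [encoder_config()]), `augment`.
#' @return List with `model` (trained `maf_model`) and `log` (data frame
#'   of per-epoch mean loss and learning rate).
#' @export
train_cam_stage <- function(patch_manifest, config = list()) {
  cfg <- utils::modifyList(cam_stage_defaults(), config)
  if (is.null(patch_manifest) || nrow(patch_manifest) == 0L) {
    stop_maaseg("empty patch manifest", class = "maaseg_value_error")
  }
  set.seed(cfg$seed)
  imgs <- lapply(patch_manifest$image_path, function(p) read_image(p) / 255)
  labels <- cbind(patch_manifest$gland_bit, patch_manifest$background_bit)
  px <- do.call(rbind, lapply(imgs, raster_to_mat))
  norm <- list(mean = colMeans(px), sd = pmax(apply(px, 2L, stats::sd), 1e-3))
  model <- maf_new(cfg$encoder, cfg$fuse_layers, cfg$common_dim)
  model$norm <- norm
  params <- collect_params(list(model$encoder$layers, model$proj, model$head))

  n <- length(imgs)
  steps_per_epoch <- max(1L, ceiling(n / cfg$batch_size))
  total_steps <- cfg$epochs * steps_per_epoch
  step <- 0L
  log <- data.frame(epoch = integer(0), loss = numeric(0), lr = numeric(0))
  for (epoch in seq_len(cfg$epochs)) {
    order <- sample.int(n)
    epoch_loss <- 0
    for (bstart in seq(1L, n, by = cfg$batch_size)) {
      ids <- order[bstart:min(bstart + cfg$batch_size - 1L, n)]
      zero_grads(params)
      losses <- vector("list", length(ids))
      for (j in seq_along(ids)) {
        img <- imgs[[ids[j]]]
        if (cfg$augment) img <- augment_image(img, cfg$flip_prob, cfg$crop_ratio)
        m <- sweep(sweep(raster_to_mat(img), 2L, norm$mean, "-"), 2L, norm$sd, "/")
        fw <- maf_forward(model, ad_node(m), dim(img)[1L], dim(img)[2L])
        losses[[j]] <- ad_bce_logits(fw$logits, labels[ids[j], ])
      }
      loss <- ad_scale(ad_add_list(losses), 1 / length(ids))
      ad_backward(loss)
      lr <- cosine_lr(cfg$lr, step, total_steps, cfg$min_lr)
      sgd_step(params, lr, cfg$momentum, cfg$weight_decay)
      step <- step + 1L
      epoch_loss <- epoch_loss + loss$value
    }
    log <- rbind(log, data.frame(epoch = epoch,
                                 loss = epoch_loss / steps_per_epoch,
                                 lr = cosine_lr(cfg$lr, step, total_steps,
                                                cfg$min_lr)))
    if (isTRUE(cfg$verbose)) {
      message(sprintf("cam epoch %d/%d loss %.4f", epoch, cfg$epochs,
                      log$loss[nrow(log)]))
    }
  }
  list(model = model, log = log)
}

#' Predicted image-level labels for a patch
#'
#' @param model Trained `maf_model`.
#' @param image H x W x 3 array (0-255).
#' @return Named integer vector of predicted `c(gland, background)` bits
#'   (sigmoid logit > 0.5).
#' @export
predict_image_labels <- function(model, image) {
  d <- dim(image)
  fw <- maf_forward(model, ad_node(normalize_image(model, image)), d[1L], d[2L])
  stats::setNames(as.integer(sigmoid(as.numeric(fw$logits$value)) > 0.5),
                  c("gland", "background"))
}

#' Generate a class activation map for a patch
#'
#' The classifier-head response before pooling is rectified at zero and
#' min-max normalized per class to \[0, 1\] (a channel with zero range is
#' set to all zeros). Channel order is fixed as \[gland, background\].
#'
#' @param model Trained `maf_model`.
#' @param image H x W x 3 array (0-255).
#' @param out_size Optional `c(height, width)`; if given, the map is
#'   bilinearly upsampled to that size (e.g. the patch resolution).
#' @return List of class `class_activation_map`: `scores` (h x w x 2
#'   array in \[0, 1\]), `logits` (length-2 vector), `fused` (fused
#'   feature array used downstream by the affinity head).
#' @export
generate_cam <- function(model, image, out_size = NULL) {
  d <- dim(image)
  fw <- maf_forward(model, ad_node(normalize_image(model, image)), d[1L], d[2L])
  sc <- pmax(fw$score$value, 0)
  for (k in seq_len(ncol(sc))) {
    rng <- range(sc[, k])
    sc[, k] <- if (rng[2L] > rng[1L]) (sc[, k] - rng[1L]) / (rng[2L] - rng[1L]) else 0
  }
  scores <- mat_to_raster(sc, fw$Sh, fw$Sw)
  if (!is.null(out_size)) {
    scores <- clamp(bilinear_resize(scores, out_size[1L], out_size[2L]), 0, 1)
  }
  structure(list(scores = scores,
                 logits = stats::setNames(as.numeric(fw$logits$value),
                                          c("gland", "background")),
                 fused = mat_to_raster(fw$fused$value, fw$Sh, fw$Sw)),
            class = "class_activation_map")
}

#' Stitched class activation map for a whole tile
#'
#' Runs [generate_cam()] on every patch of the sliding-window grid,
#' gates each patch's channels by its predicted image-level bits, and
#' stitches scores and fused features back to tile size by averaging
#' overlaps (the same merge used for predictions). The result is returned
#' at the tile's 1/16-scale CAM grid, ready for [refine_pseudo_label()].
#'
#' @param model Trained `maf_model`.
#' @param image H x W x 3 tile (0-255).
#' @param patch_size,stride Sliding-window geometry (defaults 112/56).
#' @return A `class_activation_map` for the tile (scores and fused
#'   features at `ceiling(H/16)` x `ceiling(W/16)`; `logits` are the
#'   per-class maxima over patches).
#' @export
generate_cam_tile <- function(model, image, patch_size = 112L, stride = 56L) {
  d <- dim(image)
  grid <- compute_patch_grid(d[2L], d[1L], patch_size, stride)
  patches <- crop_patches(image, grid)
  score_ps <- vector("list", length(patches))
  fused_ps <- vector("list", length(patches))
  logit_mat <- matrix(0, length(patches), 2L)
  for (k in seq_along(patches)) {
    cam <- generate_cam(model, patches[[k]]$data,
                        out_size = c(patch_size, patch_size))
    score_ps[[k]] <- gated_scores(cam)
    fused_ps[[k]] <- clamp(bilinear_resize(cam$fused, patch_size, patch_size),
                           -1e6, 1e6)
    logit_mat[k, ] <- cam$logits
  }
  scores_full <- stitch_patches(score_ps, grid)
  fused_full <- stitch_patches(fused_ps, grid)
  sh <- as.integer(ceiling(d[1L] / 16)); sw <- as.integer(ceiling(d[2L] / 16))
  P <- pool_matrix(d[1L], d[2L], sh, sw)
  structure(list(scores = clamp(mat_to_raster(as.matrix(P %*% raster_to_mat(scores_full)),
                                              sh, sw), 0, 1),
                 logits = stats::setNames(apply(logit_mat, 2L, max),
                                          c("gland", "background")),
                 fused = mat_to_raster(as.matrix(P %*% raster_to_mat(fused_full)),
                                       sh, sw)),
            class = "class_activation_map")
}
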