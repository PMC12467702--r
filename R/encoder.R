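#' Hierarchical transformer encoder configuration
#'
#' Six layers, each an overlapping patch-merging downsampler followed by
#' `blocks_per_layer` repetitions of (efficient self-attention, Mix-FFN).
#' Layer i produces a feature map at 1/2^(i+1) of the input resolution
#' (1/4, 1/8, 1/16, 1/32, 1/64, 1/128), with non-integer divisions
#' resolved by ceiling via padded strided convolutions. No positional
#' encoding parameters exist; locality enters through the overlapping
#' merges and the 3x3 depthwise convolution inside each Mix-FFN.
#'
#' @param preset `"tiny"` (channels 8..48, desk scale) or `"large"`
#'   (channels 64..320).
#' @param channels Six per-layer channel depths.
#' @param heads Six per-layer attention head counts (must divide channels).
#' @param reduction Six per-layer spatial reduction ratios for the
#'   attention key/value token set.
#' @param blocks_per_layer Attention+FFN repetitions per layer (default 2).
#' @param ffn_expansion Mix-FFN hidden expansion factor.
#' @return A list of class `encoder_config`.
#' @export
encoder_config <- function(preset = c("tiny", "large"),
                           channels = NULL, heads = NULL, reduction = NULL,
                           blocks_per_layer = 2L, ffn_expansion = 4L) {
  preset <- match.arg(preset)
  defaults <- switch(preset,
    tiny = list(channels = c(8L, 16L, 24L, 32L, 40L, 48L),
                heads = c(1L, 2L, 2L, 4L, 4L, 4L)),
    large = list(channels = c(64L, 128L, 192L, 256L, 288L, 320L),
                 heads = c(1L, 2L, 4L, 8L, 8L, 8L)))
  cfg <- list(channels = as.integer(channels %||% defaults$channels),
              heads = as.integer(heads %||% defaults$heads),
              reduction = as.integer(reduction %||% c(8L, 4L, 2L, 1L, 1L, 1L)),
              blocks_per_layer = as.integer(blocks_per_layer),
              ffn_expansion = as.integer(ffn_expansion),
              strides = c(4L, 2L, 2L, 2L, 2L, 2L),
              kernels = c(7L, 3L, 3L, 3L, 3L, 3L))
  for (f in c("channels", "heads", "reduction")) {
    if (length(cfg[[f]]) != 6L) {
      stop_maaseg(f, " must have six entries", class = "maaseg_config_error")
    }
  }
  if (any(cfg$channels <= 0L)) {
    stop_maaseg("channel depths must be positive", class = "maaseg_config_error")
  }
  if (any(cfg$channels %% cfg$heads != 0L)) {
    stop_maaseg("channels must be divisible by heads at every layer",
                class = "maaseg_config_error")
  }
  class(cfg) <- "encoder_config"
  cfg
}

# Build encoder parameters under the caller's RNG state.
encoder_new <- function(config) {
  layers <- vector("list", 6L)
  cin <- 3L
  for (i in 1:6) {
    cout <- config$channels[i]
    blocks <- vector("list", config$blocks_per_layer)
    for (b in seq_len(config$blocks_per_layer)) {
      blocks[[b]] <- list(attn = new_attention(cout, config$heads[i]),
                          ffn = new_mixffn(cout, config$ffn_expansion))
    }
    layers[[i]] <- list(merge = new_conv(cin, cout, config$kernels[i],
                                         passthrough = TRUE),
                        blocks = blocks)
    cin <- cout
  }
  structure(list(layers = layers, config = config), class = "maaseg_encoder")
}

#' Overlapping patch merging
#'
#' Downsamples a feature raster by `stride` with a strided convolution
#' whose kernel exceeds the stride (7x7 for stride 4, 3x3 for stride 2),
#' so adjacent output positions see overlapping input windows. Output
#' spatial dims are the ceiling of input dims / stride.
#'
#' @param feature_raster h x w x C numeric array.
#' @param stride 2 or 4.
#' @param out_channels Output channel depth.
#' @param weights Optional list(W, b) as built by the encoder; fresh random
#'   weights are drawn if omitted.
#' @return h' x w' x out_channels array.
#' @export
overlap_patch_merge <- function(feature_raster, stride, out_channels,
                                weights = NULL) {
  if (!stride %in% c(2L, 4L)) {
    stop_maaseg("stride must be 2 or 4", class = "maaseg_config_error")
  }
  d <- dim(feature_raster)
  k <- if (stride == 4L) 7L else 3L
  p <- weights %||% new_conv(d[3L], out_channels, k)
  x <- ad_node(raster_to_mat(feature_raster))
  out <- ad_conv2d(x, p$W, p$b, d[1L], d[2L], k, stride)
  mat_to_raster(out$value, out$h, out$w)
}

#' Apply one efficient self-attention block to a feature raster
#'
#' Pre-norm residual multi-head self-attention; the key/value token set is
#' spatially reduced by `reduction` per axis (adaptive average pooling),
#' keeping the attention cost linear in the query count. Attention weights
#' are non-negative and sum to one per query.
#'
#' @param feature_raster h x w x C numeric array.
#' @param heads Number of attention heads (must divide C).
#' @param reduction Key/value spatial reduction ratio (1 disables).
#' @param weights Optional block parameters as built by the encoder.
#' @return h x w x C array; attribute `"attention"` holds the per-head
#'   query-by-key attention weight matrices.
#' @export
attention_block <- function(feature_raster, heads = 1L, reduction = 1L,
                            weights = NULL) {
  d <- dim(feature_raster)
  p <- weights %||% new_attention(d[3L], heads)
  x <- ad_node(raster_to_mat(feature_raster))
  out <- attention_forward(x, p, d[1L], d[2L], reduction)
  structure(mat_to_raster(out$value, d[1L], d[2L]), attention = out$attn)
}

#' Apply one Mix-FFN block to a feature raster
#'
#' Residual feed-forward block: channel expansion, 3x3 depthwise spatial
#' convolution, GELU, contraction, residual add.
#'
#' @param feature_raster h x w x C numeric array.
#' @param weights Optional block parameters; random if omitted.
#' @param expansion Hidden expansion factor.
#' @return h x w x C array of the same shape.
#' @export
mix_ffn_block <- function(feature_raster, weights = NULL, expansion = 4L) {
  d <- dim(feature_raster)
  p <- weights %||% new_mixffn(d[3L], expansion)
  x <- ad_node(raster_to_mat(feature_raster))
  out <- mixffn_forward(x, p, d[1L], d[2L])
  mat_to_raster(out$value, d[1L], d[2L])
}

# Full forward pass; x is an N x 3 node (normalized image), returns a list
# of six nodes each carrying $h, $w.
encoder_forward <- function(enc, x, h, w) {
  cfg <- enc$config
  pyr <- vector("list", 6L)
  cur <- x
  for (i in 1:6) {
    lay <- enc$layers[[i]]
    cur <- ad_conv2d(cur, lay$merge$W, lay$merge$b, h, w,
                     cfg$kernels[i], cfg$strides[i])
    h <- cur$h; w <- cur$w
    for (b in seq_len(cfg$blocks_per_layer)) {
      cur <- attention_forward(cur, lay$blocks[[b]]$attn, h, w, cfg$reduction[i])
      cur <- mixffn_forward(cur, lay$blocks[[b]]$ffn, h, w)
    }
    # stage-output scale normalization keeps feature magnitudes comparable
    # across depths, which the fusion head relies on
    cur <- ad_rms_global(cur)
    cur$h <- h; cur$w <- w
    pyr[[i]] <- cur
  }
  pyr
}

#' Encode an image into the six-level feature pyramid
#'
#' @param model A trained or freshly initialized CAM model
#'   ([maf_new()] / [train_cam_stage()]) or a bare encoder.
#' @param image H x W x 3 numeric array on the 0-255 scale.
#' @return A list of class `feature_pyramid` with six elements, each
#'   `list(map = h x w x C array, h, w)`; level i has spatial dims
#'   `ceiling(H / 2^(i+1))` x `ceiling(W / 2^(i+1))`.
#' @export
encode <- function(model, image) {
  enc <- if (inherits(model, "maaseg_encoder")) model else model$encoder
  d <- dim(image)
  if (d[1L] < 16L || d[2L] < 16L) {
    stop_maaseg("image ", d[2L], "x", d[1L],
                " is degenerately small for the 1/4..1/128 pyramid",
                class = "maaseg_dimension_error")
  }
  x <- ad_node(normalize_image(model, image))
  pyr <- encoder_forward(enc, x, d[1L], d[2L])
  out <- lapply(pyr, function(n) {
    list(map = mat_to_raster(n$value, n$h, n$w), h = n$h, w = n$w)
  })
  class(out) <- "feature_pyramid"
  out
}

normalize_image <- function(model, image) {
  m <- raster_to_mat(image / 255)
  norm <- if (is.list(model)) model$norm else NULL
  if (!is.null(norm)) {
    m <- sweep(sweep(m, 2L, norm$mean, "-"), 2L, norm$sd, "/")
  }
  m
}
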