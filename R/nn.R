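# Layer constructors, forward helpers and the SGD optimizer used by the
# CAM, affinity and segmentation stages. Parameters are ad_param nodes
# collected into flat named lists so a whole model can be stepped, saved
# and restored generically.

init_weight <- function(fan_in, fan_out, gain = 2) {
  matrix(stats::rnorm(fan_in * fan_out, sd = sqrt(gain / fan_in)), fan_in, fan_out)
}

new_linear <- function(cin, cout) {
  list(W = ad_param(init_weight(cin, cout)), b = ad_param(numeric(cout)))
}

# `passthrough`: initialize the first min(3, cin, cout) output channels as
# exact center-tap copies of the corresponding input channels, so a stack
# of such convolutions starts as a strided image pyramid and downstream
# heads can immediately read local color; remaining channels are He noise.
new_conv <- function(cin, cout, k, passthrough = FALSE) {
  W <- init_weight(k * k * cin, cout)
  if (passthrough) {
    npt <- min(3L, cin, cout)
    ctr <- (k + 1L) %/% 2L
    for (c in seq_len(npt)) {
      W[, c] <- W[, c] * 0.05
      W[ctr + (ctr - 1L) * k + (c - 1L) * k * k, c] <- 1
    }
  }
  list(W = ad_param(W), b = ad_param(numeric(cout)))
}

new_layernorm <- function(c) {
  list(gamma = ad_param(rep(1, c)), beta = ad_param(numeric(c)))
}

new_attention <- function(c, heads) {
  if (c %% heads != 0L) {
    stop_maaseg("channels (", c, ") not divisible by heads (", heads, ")",
                class = "maaseg_config_error")
  }
  # zero-initialized output projection (SkipInit-style): the residual
  # branch starts silent, so early training is dominated by the local
  # convolutional path and attention context grows in as it pays off
  list(ln = new_layernorm(c),
       q = new_linear(c, c), k = new_linear(c, c), v = new_linear(c, c),
       o = list(W = ad_param(matrix(0, c, c)), b = ad_param(numeric(c))),
       heads = heads)
}

new_mixffn <- function(c, expansion = 4L) {
  e <- c * expansion
  # zero-initialized contraction (SkipInit, as for attention): the
  # residual branch starts silent
  list(ln = new_layernorm(c),
       fc1 = new_linear(c, e),
       dw = list(W = ad_param(matrix(stats::rnorm(9 * e, sd = sqrt(2 / 9)), 9, e)),
                 b = ad_param(numeric(e))),
       fc2 = list(W = ad_param(matrix(0, e, c)), b = ad_param(numeric(c))))
}

# Efficient self-attention with spatial reduction of keys/values: the
# key/value token set is the input adaptively average-pooled by `reduction`
# per axis. Residual output, pre-norm. x is an N x C node at (h, w).
attention_forward <- function(x, p, h, w, reduction) {
  C <- ncol(x$value)
  heads <- p$heads
  dh <- C %/% heads
  xn <- ad_layernorm(x, p$ln$gamma, p$ln$beta)
  if (reduction > 1L) {
    rh <- as.integer(ceiling(h / reduction))
    rw <- as.integer(ceiling(w / reduction))
    xr <- ad_spmm(pool_matrix(h, w, rh, rw), xn)
  } else {
    xr <- xn
  }
  Q <- ad_add_bias(ad_matmul(xn, p$q$W), p$q$b)
  K <- ad_add_bias(ad_matmul(xr, p$k$W), p$k$b)
  V <- ad_add_bias(ad_matmul(xr, p$v$W), p$v$b)
  outs <- vector("list", heads)
  attn <- vector("list", heads)
  for (hh in seq_len(heads)) {
    cols <- (hh - 1L) * dh + seq_len(dh)
    Qh <- ad_cols(Q, cols)
    Kh <- ad_cols(K, cols)
    Vh <- ad_cols(V, cols)
    A <- ad_softmax_rows(ad_scale(ad_matmul(Qh, ad_transpose(Kh)), 1 / sqrt(dh)))
    attn[[hh]] <- A$value
    outs[[hh]] <- ad_matmul(A, Vh)
  }
  O <- if (heads > 1L) ad_cbind(outs) else outs[[1L]]
  out <- ad_add(x, ad_add_bias(ad_matmul(O, p$o$W), p$o$b))
  out$h <- h
  out$w <- w
  out$attn <- attn
  out
}

ad_transpose <- function(x) {
  out <- ad_node(t(x$value), list(x))
  out$backward <- function(n) ad_accum(x, t(n$grad))
  out
}

# Mix-FFN: expand, 3x3 depthwise spatial convolution, GELU, contract,
# residual add. Injects local positional cues without positional encodings.
mixffn_forward <- function(x, p, h, w) {
  xn <- ad_layernorm(x, p$ln$gamma, p$ln$beta)
  z <- ad_add_bias(ad_matmul(xn, p$fc1$W), p$fc1$b)
  z <- ad_depthwise3x3(z, p$dw$W, p$dw$b, h, w)
  z <- ad_gelu(z)
  z <- ad_add_bias(ad_matmul(z, p$fc2$W), p$fc2$b)
  out <- ad_add(x, z)
  out$h <- h
  out$w <- w
  out
}

# Mean binary cross-entropy over classes from logits; targets constant 0/1.
ad_bce_logits <- function(logits, targets) {
  z <- as.numeric(logits$value)
  t <- as.numeric(targets)
  sp <- pmax(z, 0) + log1p(exp(-abs(z)))   # stable softplus
  out <- ad_node(mean(sp - t * z), list(logits))
  out$backward <- function(n) {
    g <- as.numeric(n$grad) * (sigmoid(z) - t) / length(z)
    ad_accum(logits, matrix(g, nrow(logits$value), ncol(logits$value)))
  }
  out
}

# ---- parameter bookkeeping --------------------------------------------------

collect_params <- function(x) {
  if (is_ad(x)) return(if (x$is_param) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

sgd_step <- function(params, lr, momentum = 0.9, weight_decay = 0,
                     clip_norm = Inf) {
  if (is.finite(clip_norm)) {
    total <- sqrt(sum(vapply(params, function(p) {
      if (is.null(p$grad)) 0 else sum(p$grad^2)
    }, numeric(1))))
    if (total > clip_norm) {
      for (p in params) if (!is.null(p$grad)) p$grad <- p$grad * (clip_norm / total)
    }
  }
  for (p in params) {
    if (is.null(p$grad)) next
    g <- p$grad
    if (weight_decay > 0) g <- g + weight_decay * p$value
    if (momentum > 0) {
      if (is.null(p$mom)) p$mom <- array(0, dim = dim(g) %||% length(g))
      p$mom <- momentum * p$mom + g
      g <- p$mom
    }
    p$value <- p$value - lr * g
  }
  invisible(NULL)
}

cosine_lr <- function(base_lr, step, total_steps, min_lr = 0) {
  min_lr + (base_lr - min_lr) * 0.5 * (1 + cos(pi * min(step, total_steps) / total_steps))
}

# Serialize parameter values (plain numeric) for checkpointing.
params_values <- function(x) {
  if (is_ad(x)) return(x$value)
  if (is.list(x)) return(lapply(x, params_values))
  x
}

params_restore <- function(skeleton, values) {
  if (is_ad(skeleton)) {
    skeleton$value <- values
    return(invisible(NULL))
  }
  if (is.list(skeleton)) {
    for (nm in seq_along(skeleton)) params_restore(skeleton[[nm]], values[[nm]])
  }
  invisible(NULL)
}
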