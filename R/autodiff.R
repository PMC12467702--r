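# Minimal reverse-mode automatic differentiation on dense numeric
# matrices/arrays. Internal: powers the encoder, the affinity head and the
# segmentation network. A node is an environment holding a value, an
# accumulated gradient, its parent nodes and a backward closure that
# distributes the node's gradient to the parents. Graphs are rebuilt every
# forward pass; only parameter nodes persist across passes.

.ad_counter <- new.env(parent = emptyenv())
.ad_counter$id <- 0L

ad_node <- function(value, parents = list(), backward = NULL) {
  e <- new.env(parent = emptyenv())
  .ad_counter$id <- .ad_counter$id + 1L
  e$id <- .ad_counter$id
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backward <- backward
  e$is_param <- FALSE
  e$is_node <- TRUE   # marker instead of a class: avoids S3 dispatch on $
  e
}

ad_param <- function(value) {
  n <- ad_node(value)
  n$is_param <- TRUE
  n
}

is_ad <- function(x) is.environment(x) && isTRUE(x$is_node)

# Accumulate gradient into a node; constant leaves are skipped to save work.
ad_accum <- function(node, g) {
  if (is.null(node$backward) && !node$is_param) return(invisible(NULL))
  node$grad <- if (is.null(node$grad)) g else node$grad + g
  invisible(NULL)
}

ad_needs_grad <- function(node) node$is_param || !is.null(node$backward)

ad_backward <- function(root) {
  stamp <- .ad_counter$id + 1L   # unique per call; node ids never reach it again
  .ad_counter$id <- stamp
  # iterative post-order DFS (gray/black) -> topological order, inputs first
  stack <- vector("list", 1024L)
  stack[[1L]] <- root
  sp <- 1L
  topo <- vector("list", 1024L)
  nt <- 0L
  while (sp > 0L) {
    node <- stack[[sp]]
    if (!identical(node$vstamp, stamp)) {        # white: expand
      node$vstamp <- stamp
      node$vdone <- FALSE
      for (p in node$parents) {
        if (!identical(p$vstamp, stamp)) {
          sp <- sp + 1L
          if (sp > length(stack)) stack <- c(stack, vector("list", length(stack)))
          stack[[sp]] <- p
        }
      }
    } else if (!node$vdone) {                    # gray: parents finished
      node$vdone <- TRUE
      sp <- sp - 1L
      nt <- nt + 1L
      if (nt > length(topo)) topo <- c(topo, vector("list", length(topo)))
      topo[[nt]] <- node
    } else {                                     # black via another path
      sp <- sp - 1L
    }
  }
  root$grad <- array(1, dim = dim(root$value) %||% length(root$value))
  for (i in rev(seq_len(nt))) {
    node <- topo[[i]]
    if (!is.null(node$backward) && !is.null(node$grad)) node$backward(node)
  }
  invisible(NULL)
}

# ---- elementary ops ---------------------------------------------------------

ad_add <- function(a, b) {
  out <- ad_node(a$value + b$value, list(a, b))
  out$backward <- function(n) {
    ad_accum(a, n$grad)
    ad_accum(b, n$grad)
  }
  out
}

# Sum of many scalar nodes in one graph node (keeps graph depth shallow).
ad_add_list <- function(nodes) {
  out <- ad_node(sum(vapply(nodes, function(n) n$value, numeric(1))), nodes)
  out$backward <- function(n) for (p in nodes) ad_accum(p, n$grad)
  out
}

ad_scale <- function(x, k) {
  out <- ad_node(x$value * k, list(x))
  out$backward <- function(n) ad_accum(x, n$grad * k)
  out
}

# Elementwise product with a constant (masks, detached weight maps).
ad_mul_const <- function(x, m) {
  out <- ad_node(x$value * m, list(x))
  out$backward <- function(n) ad_accum(x, n$grad * m)
  out
}

ad_matmul <- function(a, b) {
  out <- ad_node(a$value %*% b$value, list(a, b))
  out$backward <- function(n) {
    ad_accum(a, n$grad %*% t(b$value))
    ad_accum(b, crossprod(a$value, n$grad))
  }
  out
}

# x: N x C node, bias: length-C parameter.
ad_add_bias <- function(x, b) {
  bv <- as.numeric(b$value)
  out <- ad_node(sweep(x$value, 2L, bv, "+"), list(x, b))
  out$backward <- function(n) {
    ad_accum(x, n$grad)
    ad_accum(b, colSums(n$grad))
  }
  out
}

ad_relu <- function(x) {
  v <- x$value
  out <- ad_node(pmax(v, 0), list(x))
  out$backward <- function(n) ad_accum(x, n$grad * (v > 0))
  out
}

ad_leaky_relu <- function(x, alpha = 0.01) {
  v <- x$value
  out <- ad_node(pmax(v, alpha * v), list(x))
  out$backward <- function(n) {
    ad_accum(x, n$grad * ifelse(v > 0, 1, alpha))
  }
  out
}

ad_gelu <- function(x) {
  v <- x$value
  out <- ad_node(v * stats::pnorm(v), list(x))
  out$backward <- function(n) {
    ad_accum(x, n$grad * (stats::pnorm(v) + v * stats::dnorm(v)))
  }
  out
}

ad_sigmoid <- function(x) {
  s <- sigmoid(x$value)
  out <- ad_node(s, list(x))
  out$backward <- function(n) ad_accum(x, n$grad * s * (1 - s))
  out
}

row_max <- function(m) {
  out <- m[, 1L]
  for (k in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, k])
  out
}

ad_softmax_rows <- function(x) {
  v <- x$value
  v <- v - row_max(v)
  e <- exp(v)
  s <- e / rowSums(e)
  out <- ad_node(s, list(x))
  out$backward <- function(n) {
    g <- n$grad
    ad_accum(x, s * (g - rowSums(g * s)))
  }
  out
}

# Row-wise layer normalization over channels with learned gain/shift.
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  v <- x$value
  mu <- rowMeans(v)
  xc <- v - mu
  va <- rowMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * inv
  gv <- as.numeric(gamma$value)
  y <- sweep(xhat, 2L, gv, "*")
  y <- sweep(y, 2L, as.numeric(beta$value), "+")
  out <- ad_node(y, list(x, gamma, beta))
  out$backward <- function(n) {
    g <- n$grad
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * inv
    ad_accum(x, dx)
    ad_accum(gamma, colSums(g * xhat))
    ad_accum(beta, colSums(g))
  }
  out
}

# Global RMS normalization: divides the whole map by the scalar root mean
# square of its entries. Keeps feature scales comparable across encoder
# depths without per-token renormalization (which would amplify
# low-variance tokens, e.g. at zero-padded borders).
ad_rms_global <- function(x, eps = 1e-6) {
  v <- x$value
  r <- sqrt(mean(v * v) + eps)
  y <- v / r
  out <- ad_node(y, list(x))
  out$backward <- function(n) {
    g <- n$grad
    ad_accum(x, (g - y * (sum(g * y) / length(y))) / r)
  }
  out
}

# Constant (sparse) matrix times node: bilinear resize, pooling, reductions.
ad_spmm <- function(M, x) {
  out <- ad_node(as.matrix(M %*% x$value), list(x))
  out$backward <- function(n) ad_accum(x, as.matrix(Matrix::crossprod(M, n$grad)))
  out
}

ad_cols <- function(x, idx) {
  out <- ad_node(x$value[, idx, drop = FALSE], list(x))
  out$backward <- function(n) {
    g <- matrix(0, nrow(x$value), ncol(x$value))
    g[, idx] <- n$grad
    ad_accum(x, g)
  }
  out
}

ad_rows <- function(x, idx) {
  out <- ad_node(x$value[idx, , drop = FALSE], list(x))
  out$backward <- function(n) {
    g <- matrix(0, nrow(x$value), ncol(x$value))
    g[idx, ] <- g[idx, ] + n$grad
    ad_accum(x, g)
  }
  out
}

ad_cbind <- function(nodes) {
  vals <- lapply(nodes, function(n) n$value)
  widths <- vapply(vals, ncol, integer(1))
  out <- ad_node(do.call(cbind, vals), nodes)
  out$backward <- function(n) {
    at <- 0L
    for (k in seq_along(nodes)) {
      ad_accum(nodes[[k]], n$grad[, at + seq_len(widths[k]), drop = FALSE])
      at <- at + widths[k]
    }
  }
  out
}

# Spatial global average pooling: N x C -> 1 x C.
ad_colmeans <- function(x) {
  nr <- nrow(x$value)
  out <- ad_node(matrix(colMeans(x$value), 1L), list(x))
  out$backward <- function(n) {
    ad_accum(x, matrix(n$grad / nr, nr, ncol(x$value), byrow = TRUE))
  }
  out
}

ad_sum <- function(x) {
  out <- ad_node(sum(x$value), list(x))
  out$backward <- function(n) {
    ad_accum(x, array(as.numeric(n$grad), dim = dim(x$value) %||% length(x$value)))
  }
  out
}

ad_mean <- function(x) ad_scale(ad_sum(x), 1 / length(x$value))

# sum(x * v) with constant v (used for detached-weight loss averaging).
ad_dot_const <- function(x, v) {
  out <- ad_node(sum(x$value * v), list(x))
  out$backward <- function(n) ad_accum(x, as.numeric(n$grad) * v)
  out
}

# ---- spatial ops ------------------------------------------------------------

# Geometry for a padded strided convolution with "same"-style symmetric
# padding and ceiling division of the output size.
conv_geom <- function(h, w, cin, k, stride) {
  out_h <- as.integer(ceiling(h / stride))
  out_w <- as.integer(ceiling(w / stride))
  pad_h <- max((out_h - 1L) * stride + k - h, 0L)
  pad_w <- max((out_w - 1L) * stride + k - w, 0L)
  pt <- pad_h %/% 2L
  pl <- pad_w %/% 2L
  ph <- h + pad_h
  pw <- w + pad_w
  np <- out_h * out_w
  oy <- rep(seq_len(out_h), times = out_w)
  ox <- rep(seq_len(out_w), each = out_h)
  ky <- rep(seq_len(k), times = k * cin)
  kx <- rep(rep(seq_len(k), each = k), times = cin)
  kc <- rep(seq_len(cin), each = k * k)
  py <- outer((oy - 1L) * stride, ky, "+")
  px <- outer((ox - 1L) * stride, kx, "+")
  idx <- py + (px - 1L) * ph +
    matrix((kc - 1L) * ph * pw, nrow = np, ncol = length(ky), byrow = TRUE)
  g <- new.env(parent = emptyenv())
  g$out_h <- out_h; g$out_w <- out_w; g$ph <- ph; g$pw <- pw
  g$pt <- pt; g$pl <- pl; g$idx <- idx; g$h <- h; g$w <- w; g$cin <- cin
  g
}

.geom_cache <- new.env(parent = emptyenv())

conv_geom_cached <- function(h, w, cin, k, stride) {
  key <- paste(h, w, cin, k, stride, sep = "_")
  g <- .geom_cache[[key]]
  if (is.null(g)) {
    g <- conv_geom(h, w, cin, k, stride)
    .geom_cache[[key]] <- g
  }
  g
}

# Sparse scatter operator turning d(col matrix) into d(padded raster);
# built lazily on first backward pass through a geometry and cached.
conv_scatter <- function(geom) {
  if (is.null(geom$scatter)) {
    geom$scatter <- Matrix::sparseMatrix(
      i = as.vector(geom$idx), j = seq_along(geom$idx), x = 1,
      dims = c(geom$ph * geom$pw * geom$cin, length(geom$idx)))
  }
  geom$scatter
}

pad_raster <- function(m, geom) {
  xp <- array(0, dim = c(geom$ph, geom$pw, geom$cin))
  a <- m
  dim(a) <- c(geom$h, geom$w, geom$cin)
  xp[geom$pt + seq_len(geom$h), geom$pl + seq_len(geom$w), ] <- a
  xp
}

# Strided 2-D convolution via gather (im2col). x: node with N x Cin value
# laid out column-major over (y, x); W: (k*k*Cin) x Cout; b: length Cout.
ad_conv2d <- function(x, W, b, h, w, k, stride) {
  geom <- conv_geom_cached(h, w, ncol(x$value), k, stride)
  xp <- pad_raster(x$value, geom)
  col <- xp[geom$idx]
  dim(col) <- dim(geom$idx)
  val <- col %*% W$value
  val <- sweep(val, 2L, as.numeric(b$value), "+")
  out <- ad_node(val, list(x, W, b))
  out$h <- geom$out_h
  out$w <- geom$out_w
  out$backward <- function(n) {
    g <- n$grad
    ad_accum(W, crossprod(col, g))
    ad_accum(b, colSums(g))
    if (ad_needs_grad(x)) {
      if (stride == 1L && geom$ph - geom$h == k - 1L && k %% 2L == 1L) {
        # input grad of a same-padded stride-1 conv = same conv of the
        # output grad with the spatially flipped, channel-transposed kernel
        cout <- ncol(g)
        bgeom <- conv_geom_cached(geom$out_h, geom$out_w, cout, k, 1L)
        gp <- pad_raster(g, bgeom)
        colg <- gp[bgeom$idx]
        dim(colg) <- dim(bgeom$idx)
        arr <- W$value
        dim(arr) <- c(k, k, geom$cin, cout)
        arr <- aperm(arr[k:1, k:1, , , drop = FALSE], c(1L, 2L, 4L, 3L))
        dim(arr) <- c(k * k * cout, geom$cin)
        ad_accum(x, colg %*% arr)
      } else {
        gcol <- g %*% t(W$value)
        gxp <- as.numeric(conv_scatter(geom) %*% as.vector(gcol))
        dim(gxp) <- c(geom$ph, geom$pw, geom$cin)
        gx <- gxp[geom$pt + seq_len(geom$h), geom$pl + seq_len(geom$w), , drop = FALSE]
        dim(gx) <- c(geom$h * geom$w, geom$cin)
        ad_accum(x, gx)
      }
    }
  }
  out
}

# Cached gather-index matrices for the 9 shifts of a 3x3 window over a
# pad-1 raster; kernel slot k (column-major over dx 0..2, dy 0..2) reads
# the padded raster at offset (dy, dx).
dw_geom_cached <- function(h, w, C) {
  key <- paste("dw", h, w, C, sep = "_")
  g <- .geom_cache[[key]]
  if (!is.null(g)) return(g)
  ph <- h + 2L
  pw <- w + 2L
  oy <- rep(seq_len(h), times = w)
  ox <- rep(seq_len(w), each = h)
  choff <- (seq_len(C) - 1L) * ph * pw
  idx <- vector("list", 9L)
  k <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    k <- k + 1L
    idx[[k]] <- outer((oy + dy) + (ox + dx - 1L) * ph, choff, "+")
  }
  g <- list(ph = ph, pw = pw, idx = idx)
  .geom_cache[[key]] <- g
  g
}

# Depthwise 3x3 convolution (pad 1, stride 1). W: 9 x C, b: length C.
# Backward for the input uses opposite-shift gathers (shifts are
# translations, so scattering never collides).
ad_depthwise3x3 <- function(x, W, b, h, w) {
  C <- ncol(x$value)
  geom <- dw_geom_cached(h, w, C)
  xp <- array(0, dim = c(geom$ph, geom$pw, C))
  a <- x$value
  dim(a) <- c(h, w, C)
  xp[1L + seq_len(h), 1L + seq_len(w), ] <- a
  Wv <- W$value
  val <- matrix(rep(as.numeric(b$value), each = h * w), h * w, C)
  shifts <- vector("list", 9L)
  for (k in seq_len(9L)) {
    Sk <- xp[geom$idx[[k]]]
    dim(Sk) <- c(h * w, C)
    shifts[[k]] <- Sk
    val <- val + sweep(Sk, 2L, Wv[k, ], "*")
  }
  out <- ad_node(val, list(x, W, b))
  out$h <- h
  out$w <- w
  out$backward <- function(n) {
    g <- n$grad
    ad_accum(b, colSums(g))
    gW <- matrix(0, 9L, C)
    for (k in seq_len(9L)) gW[k, ] <- colSums(shifts[[k]] * g)
    ad_accum(W, gW)
    if (ad_needs_grad(x)) {
      gp <- array(0, dim = c(geom$ph, geom$pw, C))
      gm <- g
      dim(gm) <- c(h, w, C)
      gp[1L + seq_len(h), 1L + seq_len(w), ] <- gm
      gx <- matrix(0, h * w, C)
      for (k in seq_len(9L)) {
        Gk <- gp[geom$idx[[10L - k]]]   # opposite shift: (dy,dx) -> (2-dy,2-dx)
        dim(Gk) <- c(h * w, C)
        gx <- gx + sweep(Gk, 2L, Wv[k, ], "*")
      }
      ad_accum(x, gx)
    }
  }
  out
}

# ---- constant resize / pooling operators ------------------------------------

.resize_cache <- new.env(parent = emptyenv())

# Sparse row-stochastic bilinear interpolation matrix mapping an h x w
# raster (column-major rows) onto H x W, align-corners convention so that
# corner samples are preserved exactly.
bilinear_matrix <- function(h, w, H, W) {
  key <- paste("bl", h, w, H, W, sep = "_")
  M <- .resize_cache[[key]]
  if (!is.null(M)) return(M)
  src_coord <- function(n_out, n_in) {
    if (n_out == 1L || n_in == 1L) return(rep((n_in + 1) / 2, n_out))
    1 + (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1)
  }
  sy <- src_coord(H, h)
  sx <- src_coord(W, w)
  y0 <- clamp(floor(sy), 1, h); y1 <- pmin(y0 + 1, h); fy <- sy - y0
  x0 <- clamp(floor(sx), 1, w); x1 <- pmin(x0 + 1, w); fx <- sx - x0
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  out_row <- rep(seq_len(H), times = W) + (rep(seq_len(W), each = H) - 1L) * H
  Y0 <- rep(y0, times = W); Y1 <- rep(y1, times = W); FY <- rep(fy, times = W)
  X0 <- rep(x0, each = H); X1 <- rep(x1, each = H); FX <- rep(fx, each = H)
  add <- function(yy, xx, ww) {
    keep <- ww > 0
    rows <<- c(rows, out_row[keep])
    cols <<- c(cols, (yy + (xx - 1L) * h)[keep])
    vals <<- c(vals, ww[keep])
  }
  add(Y0, X0, (1 - FY) * (1 - FX))
  add(Y1, X0, FY * (1 - FX))
  add(Y0, X1, (1 - FY) * FX)
  add(Y1, X1, FY * FX)
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(H * W, h * w))
  .resize_cache[[key]] <- M
  M
}

bilinear_resize <- function(a, H, W) {
  d <- dim(a)
  m <- raster_to_mat(a)
  out <- as.matrix(bilinear_matrix(d[1L], d[2L], H, W) %*% m)
  if (length(d) == 2L) matrix(out, H, W) else mat_to_raster(out, H, W)
}

# Adaptive average pooling matrix h x w -> bh x bw (each output bin averages
# the input cells it covers; bins partition the raster as evenly as possible).
pool_matrix <- function(h, w, bh, bw) {
  key <- paste("pool", h, w, bh, bw, sep = "_")
  M <- .resize_cache[[key]]
  if (!is.null(M)) return(M)
  cuts <- function(n, b) {
    lo <- floor((seq_len(b) - 1L) * n / b) + 1L
    hi <- ceiling(seq_len(b) * n / b)
    list(lo = lo, hi = hi)
  }
  cy <- cuts(h, bh); cx <- cuts(w, bw)
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  for (bx in seq_len(bw)) for (by in seq_len(bh)) {
    ys <- cy$lo[by]:cy$hi[by]
    xs <- cx$lo[bx]:cx$hi[bx]
    cells <- as.vector(outer(ys, (xs - 1L) * h, "+"))
    r <- by + (bx - 1L) * bh
    rows <- c(rows, rep(r, length(cells)))
    cols <- c(cols, cells)
    vals <- c(vals, rep(1 / length(cells), length(cells)))
  }
  M <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(bh * bw, h * w))
  .resize_cache[[key]] <- M
  M
}
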