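# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

sigmoid <- function(x) 1 / (1 + exp(-x))

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
stop_maaseg <- function(..., class = "maaseg_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

# Column-major flattening convention used everywhere: a raster of size
# h x w (x c) maps pixel (y, x) to row y + (x - 1) * h, so that
# `dim(mat) <- c(h, w, c)` round-trips without copying.
raster_to_mat <- function(a) {
  d <- dim(a)
  if (length(d) == 2L) d <- c(d, 1L)
  m <- a
  dim(m) <- c(d[1L] * d[2L], d[3L])
  m
}

mat_to_raster <- function(m, h, w) {
  a <- m
  dim(a) <- c(h, w, ncol(m))
  a
}

# Deterministic sub-seed derivation: one user seed fans out to stages.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1000003L * as.integer(offset)) %% 2147483647L
}

is_binary_mask <- function(m) {
  is.numeric(m) && all(m %in% c(0, 1))
}
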