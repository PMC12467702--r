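# Shared helpers for the test suite; all fixtures are generated in code.

tiny_spec <- function(seed = 1L, width = 112L, height = 112L, n_glands = 1L,
                      radius_range = c(20, 40), ...) {
  synthetic_spec(seed = seed, width = width, height = height,
                 n_glands = n_glands, radius_range = radius_range, ...)
}

# Exhaustive sliding-window count oracle, written as a literal scan over
# every candidate start, independent of the package's arithmetic.
oracle_axis_count <- function(dim, patch = 112L, stride = 56L) {
  starts <- c()
  for (x in 0:(dim - patch)) {
    if (x %% stride == 0L || x == dim - patch) starts <- c(starts, x)
  }
  length(unique(starts))
}

oracle_grid_count <- function(W, H, patch = 112L, stride = 56L) {
  oracle_axis_count(W, patch, stride) * oracle_axis_count(H, patch, stride)
}

# Exhaustive double-loop pair-set oracle over all pixel pairs.
oracle_pair_sets <- function(labels, r) {
  h <- nrow(labels); w <- ncol(labels)
  n <- h * w
  pos <- 0L; neg <- 0L
  for (i in seq_len(n - 1L)) {
    yi <- (i - 1L) %% h + 1L; xi <- (i - 1L) %/% h + 1L
    for (j in (i + 1L):n) {
      yj <- (j - 1L) %% h + 1L; xj <- (j - 1L) %/% h + 1L
      if ((yi - yj)^2 + (xi - xj)^2 > r^2) next
      li <- labels[yi, xi]; lj <- labels[yj, xj]
      if (li == 255L || lj == 255L) next
      if (li == lj) pos <- pos + 1L else neg <- neg + 1L
    }
  }
  c(pos = pos, neg = neg)
}

random_mask <- function(h, w, p = 0.5) {
  matrix(as.integer(stats::runif(h * w) < p), h, w)
}

# IoU over labeled (non-255) pixels, written independently of the package.
ref_masked_iou <- function(labels, truth) {
  keep <- labels != 255L
  if (!any(keep)) return(0)
  p <- (labels == 1L)[keep]
  t <- (truth == 1L)[keep]
  u <- sum(p | t)
  if (u == 0) return(1)
  sum(p & t) / u
}
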