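# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_square_symmetric <- function(m, name = "matrix", tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop_param("%s must be a square matrix", name)
  if (max(abs(m - t(m)), na.rm = TRUE) > tol)
    stop_param("%s must be symmetric", name)
  invisible(m)
}

# Upper-triangle (i < j) index pairs of an n x n matrix, as a two-column
# integer matrix ordered column-major to match `upper.tri`.
upper_pairs <- function(n) {
  idx <- which(upper.tri(diag(n)))
  cbind(i = row(diag(n))[idx], j = col(diag(n))[idx])
}

# Values of m at the upper-triangle positions (i < j), column-major order.
upper_values <- function(m) {
  m[upper.tri(m)]
}

# Build a symmetric matrix (zero diagonal) from upper-triangle values.
sym_from_upper <- function(values, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- values
  m + t(m)
}

# Euclidean distance matrix from an n x 3 coordinate matrix.
coord_dist <- function(coords) {
  as.matrix(dist(coords))
}

# Two-sample Kolmogorov-Smirnov statistic: sup |F1 - F2| over the pooled
# sample. No ties correction needed for the sup statistic itself.
ks_statistic <- function(x, y) {
  x <- sort(x[is.finite(x)])
  y <- sort(y[is.finite(y)])
  if (!length(x) || !length(y)) return(NA_real_)
  pooled <- sort(unique(c(x, y)))
  f1 <- findInterval(pooled, x) / length(x)
  f2 <- findInterval(pooled, y) / length(y)
  max(abs(f1 - f2))
}

# Local clustering coefficient of a binary adjacency matrix
# (triangles / possible pairs of neighbours; nodes with degree < 2 get 0).
local_clustering <- function(adj) {
  k <- rowSums(adj)
  tri <- diag(adj %*% adj %*% adj)
  cc <- ifelse(k >= 2, tri / (k * (k - 1)), 0)
  as.numeric(cc)
}

# Matrix exponential of a real symmetric matrix via eigendecomposition.
expm_sym <- function(m) {
  e <- eigen(m, symmetric = TRUE)
  out <- e$vectors %*% (exp(e$values) * t(e$vectors))
  (out + t(out)) / 2
}

# Derive a child seed from a master seed, kept inside 32-bit integer range.
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k) %% 2147483647L)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  expr
}
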