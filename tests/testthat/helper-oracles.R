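# Independent brute-force oracles used to verify the implementations on
# small cases. These deliberately use naive loops / set operations, not the
# package's code paths.

# All simple graphs on n nodes, as adjacency matrices (n <= 5 is cheap).
all_graphs <- function(n) {
  n_pairs <- n * (n - 1) / 2
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  lapply(seq_len(2^n_pairs) - 1L, function(code) {
    bits <- as.integer(intToBits(code))[seq_len(n_pairs)]
    a <- matrix(0L, n, n)
    a[pairs] <- bits
    a + t(a)
  })
}

# Rich-club coefficient by explicit double loop.
oracle_phi <- function(adj, k) {
  deg <- sapply(seq_len(nrow(adj)), function(i) sum(adj[i, ]))
  sel <- which(deg > k)
  if (length(sel) < 2) return(NA_real_)
  e <- 0
  for (i in sel) for (j in sel) if (j > i && adj[i, j] > 0) e <- e + 1
  2 * e / (length(sel) * (length(sel) - 1))
}

# Weighted rich-club coefficient by explicit enumeration.
oracle_phiw <- function(w, k) {
  adj <- (w > 0) * 1
  deg <- rowSums(adj)
  sel <- which(deg > k)
  if (length(sel) < 2) return(NA_real_)
  wsum <- 0; e <- 0
  for (i in sel) for (j in sel) if (j > i && w[i, j] > 0) {
    wsum <- wsum + w[i, j]; e <- e + 1
  }
  if (e < 1) return(NA_real_)
  all_w <- sort(w[upper.tri(w)][w[upper.tri(w)] > 0], decreasing = TRUE)
  wsum / sum(all_w[seq_len(e)])
}

# Communicability by truncated power series sum_{l=0}^{lmax} A^l / l!.
oracle_communicability_series <- function(a, lmax = 20) {
  n <- nrow(a)
  out <- diag(n)
  term <- diag(n)
  for (l in seq_len(lmax)) {
    term <- term %*% a / l
    out <- out + term
  }
  out
}

# Generative-model topological terms by naive per-pair set operations.
oracle_topological_term <- function(adj, rule) {
  n <- nrow(adj)
  deg <- rowSums(adj)
  clust <- sapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) < 2) return(0)
    links <- 0
    for (u in nb) for (v in nb) if (v > u && adj[u, v] > 0) links <- links + 1
    2 * links / (length(nb) * (length(nb) - 1))
  })
  t_ij <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    t_ij[i, j] <- switch(rule,
      sptl = 1,
      `deg-avg` = (deg[i] + deg[j]) / 2,
      `deg-diff` = abs(deg[i] - deg[j]),
      `deg-max` = max(deg[i], deg[j]),
      `deg-min` = min(deg[i], deg[j]),
      `deg-prod` = deg[i] * deg[j],
      `clu-avg` = (clust[i] + clust[j]) / 2,
      `clu-diff` = abs(clust[i] - clust[j]),
      `clu-max` = max(clust[i], clust[j]),
      `clu-min` = min(clust[i], clust[j]),
      `clu-prod` = clust[i] * clust[j],
      neighbors = length(intersect(which(adj[i, ] > 0), which(adj[j, ] > 0))),
      matching = {
        ni <- setdiff(which(adj[i, ] > 0), j)
        nj <- setdiff(which(adj[j, ] > 0), i)
        u <- length(union(ni, nj))
        if (u == 0) 0 else length(intersect(ni, nj)) / u
      })
  }
  t_ij
}

# Two-sample KS statistic by double loop over the pooled sample.
oracle_ks <- function(x, y) {
  best <- 0
  for (v in c(x, y)) {
    d <- abs(mean(x <= v) - mean(y <= v))
    if (d > best) best <- d
  }
  best
}

# Method-of-moments ACE solution from twin pairs only (saturated MZ/DZ
# covariances): a2 = 2(covMZ - covDZ), c2 = 2 covDZ - covMZ.
oracle_mom_ace <- function(mz1, mz2, dz1, dz2) {
  v <- var(c(mz1, mz2, dz1, dz2))
  cmz <- cov(mz1, mz2)
  cdz <- cov(dz1, dz2)
  a2 <- 2 * (cmz - cdz)
  c2 <- 2 * cdz - cmz
  e2 <- v - a2 - c2
  std <- c(a2 = a2, c2 = c2, e2 = e2) / (a2 + c2 + e2)
  std
}

# Chi-square goodness of fit of a degree sample against Binomial(n-1, p),
# pooling the tails; returns the p-value.
oracle_binom_gof <- function(deg, n_nodes, p) {
  br <- unique(qbinom(c(0.05, 0.25, 0.5, 0.75, 0.95), n_nodes - 1, p))
  obs <- table(cut(deg, c(-1, br, n_nodes)))
  expp <- diff(c(0, pbinom(c(br, n_nodes), n_nodes - 1, p)))
  chi <- sum((obs - length(deg) * expp)^2 / (length(deg) * expp))
  1 - pchisq(chi, length(obs) - 1)
}
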