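# Transcriptional coupling: scaled-robust-sigmoid normalization, correlated
# gene expression (CGE) with exponential distance correction, per-gene
# contribution scores, cell-marker derivation, and gene-score-resampling
# enrichment.

srs_axis <- function(x) {
  # robust sigmoid + unit rescale of one vector; zero-IQR maps to 0.5
  med <- median(x, na.rm = TRUE)
  iqr <- diff(quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE,
                       type = 7))
  if (!is.finite(iqr) || iqr == 0)
    return(list(values = rep(0.5, length(x)), flagged = TRUE))
  s <- 1 / (1 + exp(-(x - med) / (iqr / 1.35)))
  rng <- range(s, na.rm = TRUE)
  if (rng[1] == rng[2])
    return(list(values = rep(0.5, length(x)), flagged = TRUE))
  list(values = (s - rng[1]) / (rng[2] - rng[1]), flagged = FALSE)
}

#' Scaled robust sigmoid normalization of an expression table
#'
#' Two passes: each value is mapped through the robust sigmoid
#' `1 / (1 + exp(-(x - median) / (IQR / 1.35)))` and min-max rescaled to
#' \[0, 1\], first for every sample (row) across genes, then for every gene
#' (column) across samples. Zero-IQR features map to a constant 0.5 and are
#' flagged. A list of donor matrices is normalized per donor and then
#' averaged per region (matching row names).
#'
#' @param x numeric matrix (regions/samples x genes) or a list of such
#'   matrices, one per donor, with region ids as row names.
#' @return Normalized matrix in \[0, 1\] with the same dimnames; flagged
#'   constant rows/columns are recorded in attributes `flagged_samples` /
#'   `flagged_genes`.
#' @export
srs_normalize <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    normed <- lapply(x, srs_normalize)
    regions <- sort(unique(unlist(lapply(normed, rownames))))
    genes <- colnames(normed[[1]])
    acc <- matrix(0, length(regions), length(genes),
                  dimnames = list(regions, genes))
    cnt <- acc
    for (m in normed) {
      acc[rownames(m), ] <- acc[rownames(m), ] + m
      cnt[rownames(m), ] <- cnt[rownames(m), ] + 1
    }
    return(acc / pmax(cnt, 1))
  }
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) stop_param("need >= 2 regions and >= 2 genes")
  flagged_samples <- logical(nrow(x))
  for (r in seq_len(nrow(x))) {
    ax <- srs_axis(x[r, ])
    x[r, ] <- ax$values
    flagged_samples[r] <- ax$flagged
  }
  flagged_genes <- logical(ncol(x))
  for (g in seq_len(ncol(x))) {
    ax <- srs_axis(x[, g])
    x[, g] <- ax$values
    flagged_genes[g] <- ax$flagged
  }
  attr(x, "flagged_samples") <- flagged_samples
  attr(x, "flagged_genes") <- flagged_genes
  x
}

#' Correlated gene expression (CGE) matrix
#'
#' Pearson correlation between every pair of region expression profiles
#' (pairwise-complete over genes). Regions with zero profile variance get NA
#' rows/columns.
#'
#' @param expr regions x genes matrix.
#' @return Symmetric region x region correlation matrix with unit diagonal.
#' @export
cge_matrix <- function(expr) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop_param("need at least 3 genes")
  cge <- suppressWarnings(cor(t(expr), use = "pairwise.complete.obs"))
  zv <- apply(expr, 1, function(v) var(v, na.rm = TRUE)) == 0
  cge[zv, ] <- NA_real_
  cge[, zv] <- NA_real_
  diag(cge)[!zv] <- 1
  cge
}

#' Fit the exponential distance decay of CGE
#'
#' Fits `r(d) = A * exp(-d / n) + B` to the region-pair CGE values by
#' nonlinear least squares with multiple starts over the length scale, and
#' returns the fit together with the residual matrix
#' `CGE_hat = CGE - r(d)`.
#'
#' @param cge region x region CGE matrix.
#' @param distances region x region distance matrix (mm); cortical-surface
#'   geodesic distances where available, Euclidean otherwise (record which
#'   in `distance_type`).
#' @param distance_type metadata label stored on the fit.
#' @return list of class `decay_fit`: `A`, `B`, `n`, `r` (function of
#'   distance), `residuals` (matrix, NA diagonal), `sse`, `n_pairs`,
#'   `distance_type`.
#' @export
fit_distance_decay <- function(cge, distances,
                               distance_type = c("euclidean", "geodesic")) {
  distance_type <- match.arg(distance_type)
  check_square_symmetric(distances, "distances", tol = 1e-6)
  ut <- upper.tri(cge)
  d <- distances[ut]
  y <- cge[ut]
  keep <- is.finite(d) & is.finite(y)
  d <- d[keep]; y <- y[keep]
  if (length(d) < 10) stop_param("need >= 10 region pairs to fit the decay")
  if (sd(y) < 1e-12) {
    warning("flat CGE: returning A ~ 0 with an arbitrarily wide length scale")
    fit <- list(A = 0, B = mean(y), n = max(d) * 100)
  } else {
    dat <- data.frame(d = d, y = y)
    best <- NULL
    for (n0 in stats::quantile(d, c(0.1, 0.25, 0.5, 1)) * c(1, 1, 1, 2)) {
      f <- tryCatch(
        minpack.lm::nlsLM(y ~ A * exp(-d / n) + B, data = dat,
                          start = list(A = max(y) - min(y),
                                       B = min(y), n = n0),
                          lower = c(-Inf, -Inf, 1e-6),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (is.null(f)) next
      sse <- sum(resid(f)^2)
      if (is.null(best) || sse < best$sse)
        best <- list(coef = coef(f), sse = sse)
    }
    if (is.null(best))
      stop("distance-decay fit failed to converge from all starts")
    fit <- as.list(best$coef)
  }
  r_fun <- function(d) fit$A * exp(-d / fit$n) + fit$B
  res <- cge - r_fun(distances)
  diag(res) <- NA_real_
  structure(list(A = fit$A, B = fit$B, n = fit$n, r = r_fun,
                 residuals = res,
                 sse = sum((y - r_fun(d))^2), n_pairs = length(d),
                 distance_type = distance_type),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf("<decay_fit> r(d) = %.4f * exp(-d / %.2f) + %.4f  (%d pairs, %s distances)\n",
              x$A, x$n, x$B, x$n_pairs, x$distance_type))
  invisible(x)
}

# z-score expression within each region across genes, population (1/N)
# divisor: the convention under which (1/N) sum_a z_i^a z_j^a equals the
# Pearson CGE between regions i and j exactly. A single-gene table is
# degenerate for this convention and is z-scored across regions instead.
zscore_regions <- function(expr) {
  n_genes <- ncol(expr)
  if (n_genes == 1) {
    mu <- mean(expr)
    s <- sqrt(sum((expr - mu)^2) / length(expr))
    if (s == 0) stop_param("zero-variance gene")
    return((expr - mu) / s)
  }
  mu <- rowMeans(expr)
  s <- sqrt(rowSums((expr - mu)^2) / n_genes)
  if (any(s == 0)) stop_param("zero-variance region profile")
  (expr - mu) / s
}

#' Gene contribution scores (GCS)
#'
#' For gene a and a region pair (i, j),
#' `GCS_ij^a = z_i^a * z_j^a - r(d_ij)`, where z is the region-wise
#' standardized expression (population divisor, so the mean over genes of
#' GCS equals the distance-residualized CGE exactly) and r is the fitted
#' distance trend. Zero-variance genes are excluded and recorded.
#'
#' @param expr regions x genes (normalized) expression matrix.
#' @param decay a `decay_fit`.
#' @param edges data.frame with 1-based region indices `i`, `j` (e.g. from
#'   [connectome_edges()]).
#' @param distances region x region distance matrix used to evaluate r(d).
#' @return edges x genes matrix of GCS values; excluded gene names in
#'   attribute `excluded_genes`.
#' @export
gene_contribution_scores <- function(expr, decay, edges, distances) {
  stopifnot(inherits(decay, "decay_fit"))
  gene_sd <- apply(expr, 2, sd)
  excluded <- colnames(expr)[gene_sd == 0]
  if (length(excluded)) expr <- expr[, gene_sd > 0, drop = FALSE]
  z <- zscore_regions(expr)
  rd <- decay$r(distances[cbind(edges$i, edges$j)])
  gcs <- z[edges$i, , drop = FALSE] * z[edges$j, , drop = FALSE] - rd
  rownames(gcs) <- paste(edges$i, edges$j, sep = "_")
  attr(gcs, "excluded_genes") <- excluded
  gcs
}

#' Per-gene rich-versus-peripheral t-statistics
#'
#' Welch t-statistic of each gene's GCS on rich edges minus peripheral
#' edges; a positive value means the gene contributes more coupling to
#' hub-hub links.
#'
#' @param gcs edges x genes GCS matrix.
#' @param rich_idx,peripheral_idx row indices of the rich and peripheral
#'   edges (both non-empty; at least 2 each for a defined statistic).
#' @return data.frame: gene, t, plus group sizes as attributes.
#' @export
gcs_link_tstat <- function(gcs, rich_idx, peripheral_idx) {
  if (!length(rich_idx) || !length(peripheral_idx))
    stop_param("both edge sets must be non-empty")
  x <- gcs[rich_idx, , drop = FALSE]
  y <- gcs[peripheral_idx, , drop = FALSE]
  n1 <- nrow(x); n2 <- nrow(y)
  if (n1 < 2 || n2 < 2) {
    t <- rep(NA_real_, ncol(gcs))
  } else {
    m1 <- colMeans(x); m2 <- colMeans(y)
    v1 <- apply(x, 2, var); v2 <- apply(y, 2, var)
    se <- sqrt(v1 / n1 + v2 / n2)
    t <- (m1 - m2) / se
    t[se == 0] <- 0
  }
  out <- data.frame(gene = colnames(gcs) %||% seq_len(ncol(gcs)), t = t,
                    stringsAsFactors = FALSE)
  attr(out, "n_rich") <- n1
  attr(out, "n_peripheral") <- n2
  out
}

#' Derive cell-class marker genes
#'
#' A gene is a marker of a class when its expression there exceeds
#' `level_min` and is at least `fold_min` times its expression in every
#' other class (so multi-class assignment is impossible). Other genes are
#' labeled `"none"`.
#'
#' @param class_expr classes x genes expression matrix (>= 2 classes).
#' @param level_min minimum expression level (default 5).
#' @param fold_min minimum fold enrichment over every other class
#'   (default 4).
#' @return data.frame: gene, class.
#' @export
derive_cell_markers <- function(class_expr, level_min = 5, fold_min = 4) {
  if (nrow(class_expr) < 2) stop_param("need at least 2 cell classes")
  genes <- colnames(class_expr) %||% paste0("g", seq_len(ncol(class_expr)))
  assign <- vapply(seq_len(ncol(class_expr)), function(g) {
    v <- class_expr[, g]
    top <- which.max(v)
    others <- v[-top]
    if (v[top] > level_min && all(v[top] >= fold_min * others))
      rownames(class_expr)[top] else "none"
  }, character(1))
  data.frame(gene = genes, class = assign, stringsAsFactors = FALSE)
}

#' Gene-set enrichment by gene score resampling (GSR)
#'
#' Each retained gene set is summarized by the mean score of its genes; the
#' null is the distribution of means of `n_iter` random same-size draws
#' (without replacement) from all scored genes. Upper-tail p-values use the
#' add-one rule, and Benjamini-Hochberg adjustment is applied across
#' retained sets. Sets outside the size bounds (after restriction to scored
#' genes) are excluded and recorded.
#'
#' @param scores named numeric vector of per-gene scores.
#' @param gene_sets named list of gene-id vectors.
#' @param n_iter resampling iterations (default 1e6; reduce for quick runs).
#' @param size_bounds inclusive set-size bounds (default c(5, 100)).
#' @param seed optional integer seed.
#' @return data.frame of class `gsr_result`: set, size, mean_score, p, q;
#'   excluded set names in attribute `excluded_sets`.
#' @export
gene_score_resampling <- function(scores, gene_sets, n_iter = 1e6,
                                  size_bounds = c(5, 100), seed = NULL) {
  if (is.null(names(scores))) stop_param("scores must be named by gene")
  scores <- scores[is.finite(scores)]
  sets <- lapply(gene_sets, function(g) intersect(g, names(scores)))
  sizes <- lengths(sets)
  ok <- sizes >= size_bounds[1] & sizes <= size_bounds[2]
  excluded <- names(sets)[!ok]
  sets <- sets[ok]; sizes <- sizes[ok]
  if (!length(sets)) stop_param("no gene set within the size bounds")
  obs <- vapply(sets, function(g) mean(scores[g]), numeric(1))

  if (!is.null(seed)) set.seed(seed)
  n_genes <- length(scores)
  sc <- unname(scores)
  p <- numeric(length(sets))
  # the null depends only on the set size: resample once per unique size
  for (s in unique(sizes)) {
    null_means <- vapply(seq_len(n_iter), function(i)
      mean(sc[sample.int(n_genes, s)]), numeric(1))
    for (w in which(sizes == s))
      p[w] <- (1 + sum(null_means >= obs[w])) / (1 + n_iter)
  }
  out <- data.frame(set = names(sets), size = sizes, mean_score = obs,
                    p = p, q = p.adjust(p, "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "excluded_sets") <- excluded
  class(out) <- c("gsr_result", "data.frame")
  out
}
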