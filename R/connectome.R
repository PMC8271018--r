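# Group-connectome construction, hub/link classification, rich-club
# statistics with null models, communicability, and link-type comparison
# curves.

#' Construct a connectome object
#'
#' @param weights symmetric nonnegative matrix with zero diagonal.
#' @param nodes optional node table (id, x, y, z, module, hemisphere).
#' @param channel label for the weight channel (e.g. "SC" or "FA").
#' @return An object of class `connectome` with elements `weights`, `mask`
#'   (binary), `nodes`, `channel`.
#' @export
as_connectome <- function(weights, nodes = NULL, channel = "SC") {
  check_square_symmetric(weights, "weights")
  if (any(weights < 0, na.rm = TRUE))
    stop_param("weights must be nonnegative")
  if (any(diag(weights) != 0)) stop_param("diagonal must be zero")
  mask <- (weights > 0) * 1L
  structure(list(weights = weights, mask = mask, nodes = nodes,
                 channel = channel),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  n <- nrow(x$mask)
  m <- sum(x$mask) / 2
  cat(sprintf("<connectome> %d nodes, %d edges (density %.3f), channel %s\n",
              n, m, m / (n * (n - 1) / 2), x$channel))
  invisible(x)
}

#' Node degrees of a connectome (binary mask)
#' @param conn a `connectome`.
#' @return Integer vector of degrees.
#' @export
node_degrees <- function(conn) {
  as.integer(rowSums(conn$mask))
}

#' Edge list of a connectome
#' @param conn a `connectome`.
#' @return data.frame with 1-based node indices `i < j` and `weight`.
#' @export
connectome_edges <- function(conn) {
  idx <- which(upper.tri(conn$mask) & conn$mask > 0)
  n <- nrow(conn$mask)
  data.frame(i = row(diag(n))[idx], j = col(diag(n))[idx],
             weight = conn$weights[idx])
}

#' Cross-subject group statistic for each edge
#'
#' The statistic is computed over the subjects in which the edge is present
#' (absent edges are treated as missing, not zero).
#'
#' @param mats list of symmetric subject matrices.
#' @param stat function, e.g. `median`.
#' @param mask optional binary matrix restricting which edges are computed.
#' @return Symmetric matrix of group statistics (0 where never present or
#'   outside `mask`).
#' @export
group_edge_statistic <- function(mats, stat = stats::median, mask = NULL) {
  n <- nrow(mats[[1]])
  vals <- vapply(mats, upper_values, numeric(n * (n - 1) / 2))
  vals[vals == 0] <- NA_real_
  gv <- apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) stat(v) else 0
  })
  gv[is.na(gv)] <- 0
  out <- sym_from_upper(gv, n)
  if (!is.null(mask)) out <- out * (mask > 0)
  out
}

#' Build a group-representative connectome by consistency + density threshold
#'
#' Retains edges that are (i) present in at least `consistency_min` of
#' subjects, and (ii) rank among the top `round(density_target * n(n-1)/2)`
#' candidate edges by the cross-subject weight statistic. Ties at the
#' density boundary are broken by higher consistency, then by lower node
#' index pair, so the output is deterministic. The group weight of a
#' retained edge is the same cross-subject statistic.
#'
#' @param subject_mats list of symmetric subject matrices (one channel).
#' @param consistency_min minimum fraction of subjects an edge must appear
#'   in (default 0.30).
#' @param density_target desired connection density `tau` in (0, 1].
#' @param weight_stat cross-subject statistic (default `median`), computed
#'   over the subjects in which the edge is present.
#' @param nodes optional node table stored on the result.
#' @param channel weight-channel label.
#' @return A `connectome`; if too few consistent edges exist to reach the
#'   target density a warning reports the achieved density.
#' @export
build_group_connectome <- function(subject_mats, consistency_min = 0.30,
                                   density_target, weight_stat = stats::median,
                                   nodes = NULL, channel = "SC") {
  if (!length(subject_mats)) stop_param("need at least one subject matrix")
  n <- nrow(subject_mats[[1]])
  for (m in subject_mats) {
    check_square_symmetric(m, "subject matrix")
    if (nrow(m) != n) stop_param("all subject matrices must share a shape")
  }
  if (density_target <= 0 || density_target > 1)
    stop_param("density_target must lie in (0, 1]")

  n_pairs <- n * (n - 1) / 2
  vals <- vapply(subject_mats, upper_values, numeric(n_pairs))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = n_pairs)
  present <- vals > 0
  consistency <- rowMeans(present)
  vals[!present] <- NA_real_
  gw <- apply(vals, 1, function(v) {
    v <- v[!is.na(v)]
    if (length(v)) weight_stat(v) else 0
  })

  target_m <- round(density_target * n_pairs)
  cand <- which(consistency >= consistency_min & gw > 0)
  pairs <- upper_pairs(n)
  ord <- cand[order(-gw[cand], -consistency[cand],
                    pairs[cand, 1], pairs[cand, 2])]
  keep <- head(ord, target_m)
  if (length(keep) < target_m)
    warning(sprintf(paste("target density %.3f unreachable under the",
                          "consistency filter; achieved density %.4f"),
                    density_target, length(keep) / n_pairs))
  wv <- numeric(n_pairs)
  wv[keep] <- gw[keep]
  conn <- as_connectome(sym_from_upper(wv, n), nodes = nodes,
                        channel = channel)
  conn$consistency <- sym_from_upper(consistency, n) * conn$mask
  conn$density <- length(keep) / n_pairs
  conn
}

#' Classify edges as rich, feeder or peripheral at a degree threshold
#'
#' Hubs are nodes with degree strictly greater than `k` (degree computed on
#' the binary mask). Edges are `rich` (hub-hub), `feeder` (hub-nonhub), or
#' `peripheral` (nonhub-nonhub); the three classes partition the edge set.
#'
#' @param conn a `connectome`.
#' @param k degree threshold (>= 0).
#' @return list with `k`, `degrees`, `hubs` (indices), `edges` (data.frame
#'   i, j, class).
#' @export
classify_links <- function(conn, k) {
  if (k < 0) stop_param("k must be nonnegative")
  deg <- node_degrees(conn)
  hubs <- which(deg > k)
  ed <- connectome_edges(conn)
  hi <- ed$i %in% hubs
  hj <- ed$j %in% hubs
  ed$class <- ifelse(hi & hj, "rich", ifelse(hi | hj, "feeder", "peripheral"))
  list(k = k, degrees = deg, hubs = hubs,
       edges = ed[, c("i", "j", "class")])
}

#' Topological rich-club coefficient
#'
#' `phi(k) = 2 E_>k / (N_>k (N_>k - 1))`: the density of the subgraph of
#' nodes with degree > k. Undefined (NA) when fewer than two such nodes
#' exist.
#'
#' @param conn a `connectome` (or binary matrix).
#' @param k degree threshold.
#' @return phi(k) in \[0, 1\], or NA when undefined.
#' @export
rich_club_coefficient <- function(conn, k) {
  mask <- if (inherits(conn, "connectome")) conn$mask else (conn > 0) * 1L
  deg <- rowSums(mask)
  sel <- deg > k
  n_sel <- sum(sel)
  if (n_sel < 2) return(NA_real_)
  e_sel <- sum(mask[sel, sel]) / 2
  2 * e_sel / (n_sel * (n_sel - 1))
}

#' Weighted rich-club coefficient
#'
#' `phi_w(k) = W_>k / sum of the E_>k largest weights in the network`, where
#' `W_>k` is the total weight of edges between nodes of degree > k.
#' Undefined (NA) when the subgraph has no edges.
#'
#' @inheritParams rich_club_coefficient
#' @return phi_w(k) in (0, 1\], or NA when undefined.
#' @export
weighted_rich_club_coefficient <- function(conn, k) {
  stopifnot(inherits(conn, "connectome"))
  deg <- node_degrees(conn)
  sel <- deg > k
  if (sum(sel) < 2) return(NA_real_)
  sub <- conn$weights[sel, sel]
  e_sel <- sum(sub > 0) / 2
  if (e_sel < 1) return(NA_real_)
  w_sel <- sum(sub) / 2
  all_w <- sort(upper_values(conn$weights)[upper_values(conn$mask) > 0],
                decreasing = TRUE)
  w_sel / sum(all_w[seq_len(e_sel)])
}

#' Degree-preserving rewiring null network
#'
#' Produces a randomized binary network with exactly the degree sequence of
#' the input via double-edge swaps (no self-loops or multi-edges; infeasible
#' swaps are skipped). `swaps_per_edge * |edges|` swap trials are attempted.
#' The swap engine is igraph's degree-preserving rewiring.
#'
#' @param conn a `connectome` or binary matrix.
#' @param swaps_per_edge swap trials per edge (default 50).
#' @param seed optional integer seed.
#' @return Binary adjacency matrix with the same degree sequence.
#' @export
degree_preserving_rewire <- function(conn, swaps_per_edge = 50, seed = NULL) {
  mask <- if (inherits(conn, "connectome")) conn$mask else (conn > 0) * 1L
  with_seed(seed, {
    g <- igraph::graph_from_adjacency_matrix(mask, mode = "undirected")
    m <- igraph::ecount(g)
    if (m >= 2)
      g <- igraph::rewire(g, igraph::keeping_degseq(
        loops = FALSE, niter = swaps_per_edge * m))
    out <- as.matrix(igraph::as_adjacency_matrix(g, type = "both"))
  })
  dimnames(out) <- dimnames(mask)
  out
}

default_k_grid <- function(deg) {
  if (max(deg) - 1 < min(deg)) return(min(deg))
  seq(min(deg), max(deg) - 1)
}

# phi over a k grid given a mask whose degree sequence is `deg` (the hub sets
# are determined by `deg`, the edges by `mask`): used for both the empirical
# curve and the rewired nulls, which share the degree sequence.
phi_profile <- function(mask, deg, k_grid) {
  vapply(k_grid, function(k) {
    sel <- deg > k
    n_sel <- sum(sel)
    if (n_sel < 2) return(NA_real_)
    2 * (sum(mask[sel, sel]) / 2) / (n_sel * (n_sel - 1))
  }, numeric(1))
}

phiw_profile <- function(weights, deg, k_grid, sorted_w) {
  vapply(k_grid, function(k) {
    sel <- deg > k
    if (sum(sel) < 2) return(NA_real_)
    sub <- weights[sel, sel]
    e_sel <- sum(sub > 0) / 2
    if (e_sel < 1) return(NA_real_)
    (sum(sub) / 2) / sum(sorted_w[seq_len(e_sel)])
  }, numeric(1))
}

#' Normalized rich-club curve with permutation p-values
#'
#' Binary mode compares `phi(k)` against degree-preserving rewired nulls;
#' weighted mode compares `phi_w(k)` against nulls that permute the edge
#' weights while keeping the binary topology fixed. Normalization is
#' `Phi_norm(k) = phi(k) / <phi_rand(k)>`, and the permutation p-value uses
#' the add-one rule `p = (1 + #\{phi_rand >= phi\}) / (1 + n_null)`, so p is
#' never 0.
#'
#' @param conn a `connectome`.
#' @param k_grid degree thresholds; defaults to all integers from the
#'   minimum degree to the maximum degree minus one.
#' @param n_null number of null networks (default 1000).
#' @param mode `"binary"` or `"weighted"`.
#' @param swaps_per_edge rewiring effort per null (binary mode).
#' @param seed optional integer seed.
#' @return data.frame of class `rich_club_curve`: k, phi, phi_rand_mean,
#'   phi_norm, p, n_null. Undefined k-points carry NA markers.
#' @export
normalized_rich_club_curve <- function(conn, k_grid = NULL, n_null = 1000,
                                       mode = c("binary", "weighted"),
                                       swaps_per_edge = 50, seed = NULL) {
  stopifnot(inherits(conn, "connectome"))
  mode <- match.arg(mode)
  if (n_null < 1) stop_param("n_null must be >= 1")
  deg <- node_degrees(conn)
  if (is.null(k_grid)) k_grid <- default_k_grid(deg)

  if (mode == "binary") {
    phi <- phi_profile(conn$mask, deg, k_grid)
    null_mat <- matrix(NA_real_, n_null, length(k_grid))
    with_seed(seed, {
      for (b in seq_len(n_null)) {
        null_mask <- degree_preserving_rewire(conn, swaps_per_edge)
        null_mat[b, ] <- phi_profile(null_mask, deg, k_grid)
      }
    })
  } else {
    wu <- upper_values(conn$weights)
    eidx <- which(wu > 0)
    sorted_w <- sort(wu[eidx], decreasing = TRUE)
    n <- nrow(conn$mask)
    phi <- phiw_profile(conn$weights, deg, k_grid, sorted_w)
    null_mat <- matrix(NA_real_, n_null, length(k_grid))
    with_seed(seed, {
      for (b in seq_len(n_null)) {
        wperm <- wu
        wperm[eidx] <- sample(wu[eidx])
        null_mat[b, ] <- phiw_profile(sym_from_upper(wperm, n), deg,
                                      k_grid, sorted_w)
      }
    })
  }
  null_mean <- colMeans(null_mat)
  p <- vapply(seq_along(k_grid), function(j) {
    if (is.na(phi[j])) return(NA_real_)
    (1 + sum(null_mat[, j] >= phi[j], na.rm = TRUE)) / (1 + n_null)
  }, numeric(1))
  out <- data.frame(k = k_grid, phi = phi, phi_rand_mean = null_mean,
                    phi_norm = phi / null_mean, p = p, n_null = n_null)
  class(out) <- c("rich_club_curve", "data.frame")
  out
}

#' Network communicability
#'
#' Binary communicability is the matrix exponential of the adjacency mask,
#' `C = exp(A)`, summing walks of every length l with weight 1/l!. Weighted
#' communicability normalizes by node strength before exponentiating:
#' `C_w = exp(S^{-1/2} W S^{-1/2})` with `S = diag(strengths)`. Isolated
#' nodes in weighted mode contribute identity rows/columns (a warning is
#' emitted).
#'
#' @param conn a `connectome` (or matrix).
#' @param mode `"binary"` or `"weighted"`.
#' @return Symmetric n x n communicability matrix.
#' @export
communicability <- function(conn, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  w <- if (inherits(conn, "connectome")) conn$weights else as.matrix(conn)
  check_square_symmetric(w, "weights")
  if (mode == "binary") return(expm_sym((w > 0) * 1))
  s <- rowSums(w)
  iso <- s <= 0
  if (any(iso)) {
    warning(sprintf("%d isolated node(s): identity contribution used",
                    sum(iso)))
    s[iso] <- 1
  }
  norm <- w / sqrt(outer(s, s))
  expm_sym(norm)
}

#' Link-type comparison curve for an edge metric
#'
#' At each degree threshold k, edges are classified as rich, feeder or
#' peripheral and the mean and SEM of an edge-level metric are computed per
#' class, together with a one-sided Welch t-test of each class against all
#' remaining edges (alternative: the class mean is greater). Classes with
#' fewer than two finite values have the test skipped (NA).
#'
#' @param conn a `connectome`.
#' @param edge_values numeric vector of the metric on the masked edges, in
#'   the order of [connectome_edges()]. Missing values allowed.
#' @param k_grid degree thresholds (default: all integers from min degree to
#'   max degree - 1).
#' @return data.frame of class `link_type_curve`: k, class, n, mean, sem, t,
#'   p, plus the network-wide mean as attribute `global_mean`.
#' @export
link_type_curve <- function(conn, edge_values, k_grid = NULL) {
  stopifnot(inherits(conn, "connectome"))
  ed <- connectome_edges(conn)
  if (length(edge_values) != nrow(ed))
    stop_param("edge_values must have one value per masked edge (%d)",
               nrow(ed))
  deg <- node_degrees(conn)
  if (is.null(k_grid)) k_grid <- default_k_grid(deg)
  classes <- c("rich", "feeder", "peripheral")
  rows <- vector("list", length(k_grid) * 3L)
  r <- 0L
  for (k in k_grid) {
    hub <- deg > k
    hi <- hub[ed$i]; hj <- hub[ed$j]
    cls <- ifelse(hi & hj, "rich",
                  ifelse(hi | hj, "feeder", "peripheral"))
    for (cl in classes) {
      v <- edge_values[cls == cl]
      v <- v[is.finite(v)]
      rest <- edge_values[cls != cl]
      rest <- rest[is.finite(rest)]
      r <- r + 1L
      if (!length(v)) {
        rows[[r]] <- data.frame(k = k, class = cl, n = 0L, mean = NA_real_,
                                sem = NA_real_, t = NA_real_, p = NA_real_)
        next
      }
      m <- mean(v)
      sem <- if (length(v) > 1) sd(v) / sqrt(length(v)) else NA_real_
      if (length(v) >= 2 && length(rest) >= 2 &&
          (sd(v) > 0 || sd(rest) > 0)) {
        tt <- t.test(v, rest, alternative = "greater")
        tv <- unname(tt$statistic); pv <- tt$p.value
      } else if (length(v) >= 2 && length(rest) >= 2) {
        # both groups constant: the t-statistic degenerates to a sign
        dm <- mean(v) - mean(rest)
        tv <- if (dm == 0) 0 else sign(dm) * Inf
        pv <- if (dm == 0) 0.5 else if (dm > 0) 0 else 1
      } else {
        tv <- NA_real_; pv <- NA_real_
      }
      rows[[r]] <- data.frame(k = k, class = cl, n = length(v), mean = m,
                              sem = sem, t = tv, p = pv)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "global_mean") <- mean(edge_values[is.finite(edge_values)])
  class(out) <- c("link_type_curve", "data.frame")
  out
}
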