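# Probabilistic growth models of connectome wiring. An edge score
# theta_ij = d_ij^eta * (t_ij + eps)^gamma combines wiring cost (Euclidean
# distance d, exponent eta <= 0 so cost is penalized) with a topological
# term t recomputed from the current adjacency at every iteration (13
# variants). Genetic variants substitute or add a transcriptional-coupling
# factor g_hat^lambda, where g_hat is residual correlated gene expression
# min-max rescaled to [eps, 1]. Edges are added one per iteration with
# probability theta / sum(theta) over the absent pairs until the target
# edge count is reached. Model fit is summarized by the maximum
# Kolmogorov-Smirnov distance across degree, clustering, betweenness and
# edge-length distributions, and by the Spearman correlation between model
# and target degree sequences.

TOPOLOGY_RULES <- c("sptl", "clu-avg", "clu-diff", "clu-max", "clu-min",
                    "clu-prod", "deg-avg", "deg-diff", "deg-max", "deg-min",
                    "deg-prod", "matching", "neighbors")
GENETIC_RULES <- c("S", "G", "SG", "TG", "ST")

#' Free parameters of a wiring rule
#'
#' @param rule a rule name (one of the 13 topological rules or the genetic
#'   variants S, G, SG, TG, ST).
#' @return Character vector among `"eta"` (wiring-cost exponent), `"gamma"`
#'   (topology exponent), `"lambda"` (transcriptional-coupling exponent).
#' @export
rule_params <- function(rule) {
  rule <- match.arg(rule, c(TOPOLOGY_RULES, GENETIC_RULES))
  switch(rule,
         sptl = "eta", S = "eta", G = "lambda",
         SG = c("eta", "lambda"), TG = c("gamma", "lambda"),
         c("eta", "gamma"))
}

default_bounds <- list(eta = c(-15, 0), gamma = c(-4, 4), lambda = c(0, 200))

# Table of topological terms t_ij, recomputed from the current adjacency.
topological_term <- function(adj, rule) {
  n <- nrow(adj)
  if (rule == "sptl") return(matrix(1, n, n))
  if (startsWith(rule, "deg")) {
    k <- rowSums(adj)
    return(switch(rule,
                  `deg-avg` = outer(k, k, `+`) / 2,
                  `deg-diff` = abs(outer(k, k, `-`)),
                  `deg-max` = outer(k, k, pmax),
                  `deg-min` = outer(k, k, pmin),
                  `deg-prod` = outer(k, k)))
  }
  if (startsWith(rule, "clu")) {
    cc <- local_clustering(adj)
    return(switch(rule,
                  `clu-avg` = outer(cc, cc, `+`) / 2,
                  `clu-diff` = abs(outer(cc, cc, `-`)),
                  `clu-max` = outer(cc, cc, pmax),
                  `clu-min` = outer(cc, cc, pmin),
                  `clu-prod` = outer(cc, cc)))
  }
  common <- adj %*% adj
  if (rule == "neighbors") return(common)
  if (rule == "matching") {
    k <- rowSums(adj)
    union <- outer(k, k, `+`) - 2 * adj - common
    t_ij <- ifelse(union > 0, common / union, 0)
    diag(t_ij) <- 0
    return(t_ij)
  }
  stop_param("unknown rule '%s'", rule)
}

# Rescale residual-CGE values to [eps, 1] over the candidate node pairs.
rescale_gexp <- function(gexp, eps) {
  g <- gexp
  diag(g) <- NA_real_
  rng <- range(g, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    out <- matrix(1, nrow(g), ncol(g))
  } else {
    out <- eps + (1 - eps) * (g - rng[1]) / (rng[2] - rng[1])
  }
  diag(out) <- NA_real_
  out
}

# log theta over all pairs for the current adjacency; genetic variants use
# t = deg-avg for their topological factor.
log_theta_matrix <- function(adj, distances, rule, params, eps, gexp_scaled) {
  eta <- params[["eta"]] %||% 0
  gamma <- params[["gamma"]] %||% 0
  lambda <- params[["lambda"]] %||% 0
  lt <- matrix(0, nrow(adj), ncol(adj))
  use_d <- rule %in% c(TOPOLOGY_RULES, "S", "SG", "ST")
  use_t <- !(rule %in% c("sptl", "S", "G", "SG"))
  use_g <- rule %in% c("G", "SG", "TG")
  if (use_d && eta != 0) lt <- lt + eta * log(distances)
  if (use_t && gamma != 0) {
    t_rule <- if (rule %in% GENETIC_RULES) "deg-avg" else rule
    lt <- lt + gamma * log(topological_term(adj, t_rule) + eps)
  }
  if (use_g && lambda != 0) lt <- lt + lambda * log(gexp_scaled)
  lt
}

#' Wiring scores and connection probabilities
#'
#' Evaluates the generative-model edge score
#' `theta_ij = d_ij^eta * (t_ij + eps)^gamma` (with the genetic variants'
#' `g_hat^lambda` factor where applicable) for the current adjacency, and
#' converts it into connection probabilities over the absent node pairs,
#' `P_ij = theta_ij / sum(theta)`.
#'
#' @param adj current binary adjacency matrix (symmetric, zero diagonal).
#' @param distances positive off-diagonal distance matrix.
#' @param rule wiring rule (see [rule_params()]).
#' @param eta,gamma,lambda exponents (only those in `rule_params(rule)` are
#'   used).
#' @param eps small positive stabilizer added inside the topological factor
#'   (default 1e-5).
#' @param gexp residual-CGE matrix, required by the genetic variants.
#' @return list: `theta` (full symmetric score matrix, NA diagonal),
#'   `candidates` (data.frame i, j, theta, p over absent pairs). If every
#'   score underflows to zero the probabilities fall back to uniform with a
#'   warning.
#' @export
wiring_scores <- function(adj, distances, rule, eta = 0, gamma = 0,
                          lambda = 0, eps = 1e-5, gexp = NULL) {
  rule <- match.arg(rule, c(TOPOLOGY_RULES, GENETIC_RULES))
  if (any(distances[upper.tri(distances)] <= 0))
    stop_param("distances must be positive off the diagonal")
  if (rule %in% c("G", "SG", "TG") && is.null(gexp))
    stop_param("rule '%s' requires a residual-CGE matrix", rule)
  gs <- if (!is.null(gexp)) rescale_gexp(gexp, eps)
  params <- list(eta = eta, gamma = gamma, lambda = lambda)
  lt <- log_theta_matrix(adj, distances, rule, params, eps, gs)
  theta <- exp(lt)
  diag(theta) <- NA_real_
  pairs <- upper_pairs(nrow(adj))
  absent <- adj[pairs] == 0
  cand <- pairs[absent, , drop = FALSE]
  th <- theta[cand]
  if (all(th == 0) || !any(is.finite(th))) {
    warning("all wiring scores vanished; falling back to uniform")
    pr <- rep(1 / nrow(cand), nrow(cand))
  } else {
    # stabilized in log space
    l <- lt[cand]
    pr <- exp(l - max(l[is.finite(l)]))
    pr[!is.finite(pr)] <- 0
    pr <- pr / sum(pr)
  }
  list(theta = theta,
       candidates = data.frame(i = cand[, 1], j = cand[, 2],
                               theta = th, p = pr))
}

#' Grow a binary network with a generative wiring rule
#'
#' Starts from an empty graph and adds one edge per iteration, sampled from
#' the current connection probabilities, until exactly `n_edges` edges
#' exist. Topological terms are recomputed each iteration; rules whose
#' scores do not depend on topology (sptl, S, G, SG) are grown by a single
#' sequential weighted draw, which is distributionally identical.
#'
#' @inheritParams wiring_scores
#' @param n_edges target edge count (at most n(n-1)/2).
#' @param seed optional integer seed; recorded on the output.
#' @return list of class `grown_network`: `adj` (binary adjacency),
#'   `order` (n_edges x 2 matrix, edges in addition order), `rule`,
#'   `params`, `seed`.
#' @export
grow_network <- function(rule, n_edges, distances, eta = 0, gamma = 0,
                         lambda = 0, eps = 1e-5, gexp = NULL, seed = NULL) {
  rule <- match.arg(rule, c(TOPOLOGY_RULES, GENETIC_RULES))
  n <- nrow(distances)
  n_pairs <- n * (n - 1) / 2
  if (n_edges > n_pairs) stop_param("n_edges exceeds the number of pairs")
  if (rule %in% c("G", "SG", "TG") && is.null(gexp))
    stop_param("rule '%s' requires a residual-CGE matrix", rule)
  gs <- if (!is.null(gexp)) rescale_gexp(gexp, eps)
  params <- list(eta = eta, gamma = gamma, lambda = lambda)
  pairs <- upper_pairs(n)
  adj <- matrix(0L, n, n)

  static <- rule %in% c("sptl", "S", "G", "SG")
  with_seed(seed, {
    if (static) {
      lt <- log_theta_matrix(adj, distances, rule, params, eps, gs)[pairs]
      w <- exp(lt - max(lt[is.finite(lt)]))
      if (all(w == 0) || !any(is.finite(w))) {
        warning("all wiring scores vanished; falling back to uniform")
        w <- rep(1, n_pairs)
      }
      picks <- sample.int(n_pairs, n_edges, replace = FALSE, prob = w)
      order_mat <- pairs[picks, , drop = FALSE]
      adj[order_mat] <- 1L
      adj[order_mat[, 2:1, drop = FALSE]] <- 1L
    } else {
      order_mat <- matrix(0L, n_edges, 2)
      absent <- rep(TRUE, n_pairs)
      for (it in seq_len(n_edges)) {
        lt <- log_theta_matrix(adj, distances, rule, params, eps, gs)[pairs]
        l <- lt[absent]
        if (!any(is.finite(l)) || all(exp(l - max(l)) == 0)) {
          w <- rep(1, sum(absent))
        } else {
          w <- exp(l - max(l[is.finite(l)]))
          w[!is.finite(w)] <- 0
        }
        pick_local <- sample.int(sum(absent), 1, prob = w)
        pick <- which(absent)[pick_local]
        absent[pick] <- FALSE
        i <- pairs[pick, 1]; j <- pairs[pick, 2]
        adj[i, j] <- adj[j, i] <- 1L
        order_mat[it, ] <- c(i, j)
      }
    }
  })
  colnames(order_mat) <- c("i", "j")
  structure(list(adj = adj, order = order_mat, rule = rule,
                 params = params[unique(c(rule_params(rule)))], seed = seed),
            class = "grown_network")
}

#' Energy report: KS fit statistics and degree-sequence correlation
#'
#' Compares a model network against a target on the node-level distributions
#' of degree, clustering and betweenness and the edge-level distribution of
#' connection distance. Each comparison is a two-sample Kolmogorov-Smirnov
#' statistic; the energy is their maximum (the worst-fitted property). The
#' spatial topography of degree is summarized separately by the Spearman
#' correlation between the two degree sequences (average ranks for ties).
#'
#' @param model_adj,target_adj binary adjacency matrices on the same node
#'   set.
#' @param distances node distance matrix (for edge lengths).
#' @return list of class `energy_report`: `ks` (named: degree, clustering,
#'   betweenness, edgelength), `energy`, `degseq_rho`.
#' @export
model_energy <- function(model_adj, target_adj, distances) {
  if (!all(dim(model_adj) == dim(target_adj)))
    stop_param("model and target must share a node set")
  stats_of <- function(adj) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    list(degree = rowSums(adj),
         clustering = local_clustering(adj),
         betweenness = igraph::betweenness(g),
         edgelength = distances[upper.tri(distances) & adj > 0])
  }
  sm <- stats_of(model_adj)
  st <- stats_of(target_adj)
  ks <- vapply(names(sm), function(nm) ks_statistic(sm[[nm]], st[[nm]]),
               numeric(1))
  structure(list(ks = ks, energy = max(ks),
                 degseq_rho = suppressWarnings(
                   cor(sm$degree, st$degree, method = "spearman"))),
            class = "energy_report")
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> energy = %.4f (KS: %s); degree-sequence rho = %.3f\n",
              x$energy,
              paste(sprintf("%s %.3f", names(x$ks), x$ks), collapse = ", "),
              x$degseq_rho))
  invisible(x)
}

#' Fit a wiring rule by preferential parameter-space sampling
#'
#' Round 1 samples parameter points uniformly inside the bounds; subsequent
#' rounds sample preferentially from the neighbourhoods (nearest-sampled-
#' point cells) of well-performing points, chosen with probability
#' proportional to the inverse rank of their objective, so the search
#' gradually concentrates where networks fit best. Each evaluation grows one
#' network and scores it; total evaluations = `n_per_round * n_rounds`.
#'
#' @param rule wiring rule.
#' @param target_adj binary target adjacency matrix.
#' @param distances node distance matrix.
#' @param n_edges edges to grow (default: the target's edge count).
#' @param n_per_round points per round (default 2000).
#' @param n_rounds sampling rounds (default 5).
#' @param objective `"energy"` (minimized) or `"degseq"` (Spearman
#'   degree-sequence correlation, maximized).
#' @param bounds named list overriding the default parameter bounds
#'   (eta in \[-15, 0\], gamma in \[-4, 4\], lambda in \[0, 200\]).
#' @param eps stabilizer passed to the growth model.
#' @param gexp residual-CGE matrix for genetic variants.
#' @param seed integer seed; per-evaluation child seeds are derived from it.
#' @return list of class `optimization_trace`: `evaluations` (data.frame:
#'   round, eval, parameters, energy, degseq_rho, objective),
#'   `per_round_best` (best objective so far at the end of each round,
#'   non-increasing), `top100` (sorted ascending objective values, up to
#'   100), `best` (parameters, objective, seed of the best evaluation).
#' @export
optimize_parameters <- function(rule, target_adj, distances, n_edges = NULL,
                                n_per_round = 2000, n_rounds = 5,
                                objective = c("energy", "degseq"),
                                bounds = NULL, eps = 1e-5, gexp = NULL,
                                seed = 1L) {
  rule <- match.arg(rule, c(TOPOLOGY_RULES, GENETIC_RULES))
  objective <- match.arg(objective)
  pnames <- rule_params(rule)
  bb <- default_bounds
  bb[names(bounds)] <- bounds
  bb <- bb[pnames]
  for (nm in pnames)
    if (diff(bb[[nm]]) <= 0) stop_param("degenerate bounds for %s", nm)
  if (is.null(n_edges)) n_edges <- sum(target_adj) / 2
  need_energy <- objective == "energy"

  set.seed(as.integer(seed))
  total <- n_per_round * n_rounds
  P <- matrix(NA_real_, total, length(pnames),
              dimnames = list(NULL, pnames))
  obj <- numeric(total)
  energy <- rep(NA_real_, total)
  rho <- numeric(total)
  round_id <- rep(seq_len(n_rounds), each = n_per_round)
  scale_rng <- vapply(bb, diff, numeric(1))

  evaluate <- function(par, k) {
    args <- c(list(rule = rule, n_edges = n_edges, distances = distances,
                   eps = eps, gexp = gexp, seed = child_seed(seed, k)),
              as.list(par))
    net <- do.call(grow_network, args)
    rep_ <- model_energy(net$adj, target_adj, distances)
    list(energy = rep_$energy, rho = rep_$degseq_rho)
  }

  done <- 0L
  for (r in seq_len(n_rounds)) {
    if (r == 1) {
      newp <- vapply(pnames, function(nm)
        runif(n_per_round, bb[[nm]][1], bb[[nm]][2]),
        numeric(n_per_round))
      newp <- matrix(newp, ncol = length(pnames))
    } else {
      prev <- P[seq_len(done), , drop = FALSE]
      prev_scaled <- sweep(prev, 2, scale_rng, "/")
      rk <- rank(obj[seq_len(done)], ties.method = "first")
      w <- 1 / rk
      newp <- matrix(NA_real_, n_per_round, length(pnames))
      picks <- sample.int(done, n_per_round, replace = TRUE, prob = w)
      for (s in seq_len(n_per_round)) {
        jj <- picks[s]
        # local cell size: scaled distance to the nearest other point
        dists <- sqrt(colSums((t(prev_scaled) - prev_scaled[jj, ])^2))
        dists[jj] <- Inf
        delta <- min(dists) * scale_rng
        cand <- prev[jj, ] + runif(length(pnames), -delta, delta)
        newp[s, ] <- pmin(pmax(cand, vapply(bb, `[`, numeric(1), 1)),
                          vapply(bb, `[`, numeric(1), 2))
      }
    }
    for (s in seq_len(n_per_round)) {
      k <- done + s
      par <- setNames(newp[s, ], pnames)
      ev <- evaluate(par, k)
      P[k, ] <- par
      energy[k] <- ev$energy
      rho[k] <- ev$rho
      obj[k] <- if (need_energy) ev$energy else -ev$rho
    }
    done <- done + n_per_round
  }

  evals <- data.frame(round = round_id, eval = seq_len(total), P,
                      energy = energy, degseq_rho = rho, objective = obj)
  per_round_best <- vapply(seq_len(n_rounds), function(r)
    min(obj[round_id <= r]), numeric(1))
  top <- sort(obj)[seq_len(min(100, total))]
  ib <- which.min(obj)
  structure(list(evaluations = evals, per_round_best = per_round_best,
                 top100 = top,
                 best = list(rule = rule, params = setNames(P[ib, ], pnames),
                             objective = obj[ib], energy = energy[ib],
                             degseq_rho = rho[ib],
                             seed = child_seed(seed, ib))),
            class = "optimization_trace")
}

#' @export
print.optimization_trace <- function(x, ...) {
  cat(sprintf("<optimization_trace> %d evaluations; best %s = %.4f at (%s)\n",
              nrow(x$evaluations),
              if (is.na(x$best$energy)) "objective" else "energy",
              x$best$objective,
              paste(sprintf("%s=%.3g", names(x$best$params),
                            x$best$params), collapse = ", ")))
  invisible(x)
}
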