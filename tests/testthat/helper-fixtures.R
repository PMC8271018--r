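# Shared synthetic fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

memo_fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Planted rich-club cohort at low density: hubs clearly top-degree, hub-hub
# edges saturated, used by the rich-club detection tests.
richclub_fixture <- function() {
  memo_fixture("richclub", function() {
    spec <- cohort_spec(n_nodes = 150, n_subjects = 30, hub_fraction = 0.09,
                        richclub_boost = 0.9, hub_degree_boost = 0.05,
                        decay_scale = 50, base_prob = 0.45, seed = 3)
    sim <- simulate_cohort_connectomes(spec)
    conn <- suppressWarnings(build_group_connectome(
      lapply(sim$subjects, `[[`, "sc"), 0.3, 0.045, nodes = sim$nodes))
    deg <- node_degrees(conn)
    planted_k <- seq(max(deg[-sim$hubs]), min(deg[sim$hubs]) - 1)
    list(sim = sim, conn = conn, hubs = sim$hubs, planted_k = planted_k)
  })
}

# Weak-geometry hub cohort with hub-boosted transcriptional coupling, used
# by the generative-model comparisons and end-to-end link-type tests.
genetic_target_fixture <- function() {
  memo_fixture("genetic_target", function() {
    spec <- cohort_spec(n_nodes = 50, n_subjects = 25, hub_fraction = 0.14,
                        richclub_boost = 0.8, hub_degree_boost = 0.2,
                        decay_scale = 400, base_prob = 0.25, seed = 13)
    sim <- simulate_cohort_connectomes(spec)
    conn <- build_group_connectome(lapply(sim$subjects, `[[`, "sc"),
                                   0.3, 0.15, nodes = sim$nodes)
    es <- expression_spec(n_genes = 500, hub_coupling_boost = 0.35,
                          noise_sd = 0.02, seed = 14)
    ex <- simulate_expression(es, sim$nodes, sim$hubs)
    r_true <- es$A * exp(-ex$distances / es$n) + es$B
    gres <- cge_matrix(ex$expr) - r_true
    diag(gres) <- NA_real_
    list(sim = sim, conn = conn, hubs = sim$hubs, expr = ex, gres = gres)
  })
}

# Mid-size expression atlas over a hub cohort, used by the coupling tests.
expression_fixture <- function() {
  memo_fixture("expression", function() {
    spec <- cohort_spec(n_nodes = 100, seed = 4)
    sim <- simulate_cohort_connectomes(spec)
    es <- expression_spec(n_genes = 500, seed = 9)
    ex <- simulate_expression(es, sim$nodes, sim$hubs)
    atlas <- srs_normalize(ex$expr)
    cge <- cge_matrix(atlas)
    decay <- fit_distance_decay(cge, ex$distances)
    list(sim = sim, ex = ex, atlas = atlas, cge = cge, decay = decay)
  })
}

# Small random weighted connectome for interface-level tests.
toy_connectome <- function(n = 12, p = 0.4, seed = 7) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  w[ut] <- ifelse(runif(sum(ut)) < p, rlnorm(sum(ut)), 0)
  as_connectome(w + t(w))
}
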