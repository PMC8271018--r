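test_that("wiring scores follow the cost-topology product form", {
  d <- matrix(2, 3, 3); diag(d) <- 0
  adj <- matrix(0, 3, 3)
  # direct formula with eps = 0 surrogate: theta = d^eta * (t + eps)^gamma
  ws <- wiring_scores(adj, d, "deg-avg", eta = 1, gamma = 2, eps = 3)
  # empty graph: t = 0 everywhere, so theta = 2^1 * 3^2 = 18
  expect_equal(ws$candidates$theta, rep(18, 3))
  # exponents zero: uniform probabilities over absent pairs
  u <- wiring_scores(adj, d, "deg-avg", eta = 0, gamma = 0)
  expect_equal(u$candidates$p, rep(1 / 3, 3))
  expect_error(wiring_scores(adj, matrix(0, 3, 3), "sptl"), "positive")
  expect_error(wiring_scores(adj, d, "TG"), "residual-CGE")
})

test_that("Table-2 topological terms match exhaustive enumeration on all graphs up to 5 nodes", {
  rules <- c("deg-avg", "deg-diff", "deg-max", "deg-min", "deg-prod",
             "clu-avg", "clu-diff", "clu-max", "clu-min", "clu-prod",
             "matching", "neighbors")
  for (n in c(3, 4)) {
    for (a in all_graphs(n)) {
      for (rule in rules) {
        got <- connherit:::topological_term(a, rule)
        want <- oracle_topological_term(a, rule)
        diag(want) <- diag(got)      # diagonal never used by the models
        expect_equal(got, want, tolerance = 1e-12)
      }
    }
  }
  # 5-node graphs sampled (the 4-node set is exhaustive above)
  set.seed(14)
  for (rep in 1:60) {
    a <- matrix(0, 5, 5); ut <- upper.tri(a)
    a[ut] <- rbinom(sum(ut), 1, 0.5); a <- a + t(a)
    for (rule in rules) {
      got <- connherit:::topological_term(a, rule)
      want <- oracle_topological_term(a, rule)
      diag(want) <- diag(got)
      expect_equal(got, want, tolerance = 1e-12)
    }
  }
})

test_that("matching rule reproduces hand-computed neighbour overlap on a toy graph", {
  # path 1-2-3-4 plus edge 1-3
  a <- matrix(0, 4, 4)
  a[1, 2] <- a[2, 3] <- a[3, 4] <- a[1, 3] <- 1
  a <- a + t(a)
  t_ij <- connherit:::topological_term(a, "matching")
  # nodes 1 and 2: N1\2 = {3}, N2\1 = {3} -> 1/1
  expect_equal(t_ij[1, 2], 1)
  # nodes 1 and 4: N1\4 = {2,3}, N4\1 = {3} -> |{3}| / |{2,3}| = 1/2
  expect_equal(t_ij[1, 4], 0.5)
  # nodes 2 and 4: N2\4 = {1,3}, N4\2 = {3} -> 1/2
  expect_equal(t_ij[2, 4], 0.5)
})

test_that("grown networks are simple, symmetric, with exactly E edges and recorded order", {
  set.seed(15)
  coords <- cbind(runif(30, 0, 100), runif(30, 0, 100), runif(30, 0, 100))
  d <- as.matrix(dist(coords))
  for (rule in c("sptl", "deg-avg", "matching", "clu-avg")) {
    g <- grow_network(rule, 60, d, eta = -1, gamma = 0.5, seed = 20)
    expect_equal(sum(g$adj) / 2, 60)
    expect_equal(g$adj, t(g$adj))
    expect_true(all(diag(g$adj) == 0))
    expect_equal(nrow(g$order), 60)
    expect_false(any(duplicated(g$order)))
  }
  # determinism under a fixed seed
  g1 <- grow_network("deg-avg", 40, d, eta = -1, gamma = 1, seed = 33)
  g2 <- grow_network("deg-avg", 40, d, eta = -1, gamma = 1, seed = 33)
  expect_identical(g1$adj, g2$adj)
  expect_error(grow_network("sptl", 1000, d), "exceeds")
})

test_that("strong distance penalty shortens edges; uniform rule is Erdos-Renyi", {
  set.seed(16)
  coords <- cbind(runif(60, 0, 100), runif(60, 0, 100), runif(60, 0, 100))
  d <- as.matrix(dist(coords))
  len <- function(adj) mean(d[upper.tri(d) & adj > 0])
  short <- vapply(1:20, function(s)
    len(grow_network("sptl", 150, d, eta = -8, seed = s)$adj), numeric(1))
  unif <- vapply(1:20, function(s)
    len(grow_network("sptl", 150, d, eta = 0, seed = 100 + s)$adj),
    numeric(1))
  expect_true(all(short < unif))

  deg <- unlist(lapply(1:10, function(s)
    rowSums(grow_network("sptl", 150, d, eta = 0, seed = 200 + s)$adj)))
  expect_gt(oracle_binom_gof(deg, 60, 150 / (60 * 59 / 2)), 0.01)
})

test_that("energy report matches the KS oracle and dissociates distribution from sequence", {
  set.seed(17)
  coords <- cbind(runif(20, 0, 100), runif(20, 0, 100), runif(20, 0, 100))
  d <- as.matrix(dist(coords))
  g1 <- grow_network("sptl", 50, d, eta = -2, seed = 1)
  g2 <- grow_network("sptl", 50, d, eta = 0, seed = 2)
  er <- model_energy(g1$adj, g2$adj, d)
  expect_true(all(er$ks >= 0 & er$ks <= 1))
  expect_equal(er$energy, max(er$ks))
  # network vs itself
  self <- model_energy(g1$adj, g1$adj, d)
  expect_equal(self$energy, 0)
  expect_equal(self$degseq_rho, 1)
  # KS agrees with the double-loop oracle on raw samples
  for (rep in 1:20) {
    x <- rnorm(sample(5:50, 1)); y <- rnorm(sample(5:50, 1), 0.3)
    expect_equal(connherit:::ks_statistic(x, y), oracle_ks(x, y))
  }
  # path graph relabeled in reverse: same degree distribution, rho = -1
  p <- matrix(0, 6, 6); p[cbind(1:5, 2:6)] <- 1; p <- p + t(p)
  rev_p <- p[6:1, 6:1]
  # break the symmetric tie pattern by attaching a pendant chain
  p2 <- matrix(0, 7, 7); p2[cbind(1:6, 2:7)] <- 1; p2[1, 3] <- p2[3, 1] <- 1
  p2 <- p2 + t(p2)
  er2 <- model_energy(p2[7:1, 7:1], p2, d[1:7, 1:7])
  expect_equal(er2$ks[["degree"]], 0)
  expect_lt(er2$degseq_rho, 0)
  # disjoint degree distributions: KS(degree) = 1
  ring <- matrix(0, 6, 6); ring[cbind(1:6, c(2:6, 1))] <- 1; ring <- ring + t(ring)
  k6 <- matrix(1, 6, 6) - diag(6)          # all degrees 5 vs all degrees 2
  expect_equal(model_energy(ring, k6, d[1:6, 1:6])$ks[["degree"]], 1)
})

test_that("parameter search recovers a planted spatial exponent and keeps elitist bookkeeping", {
  set.seed(18)
  coords <- cbind(runif(100, 0, 140), runif(100, 0, 170), runif(100, 0, 120))
  d <- as.matrix(dist(coords))
  target <- grow_network("sptl", round(0.2 * 100 * 99 / 2), d, eta = -3,
                         seed = 11)
  tr <- optimize_parameters("sptl", target$adj, d, n_per_round = 100,
                            n_rounds = 5, seed = 21)
  expect_equal(unname(tr$best$params["eta"]), -3, tolerance = 0.5)
  expect_true(all(diff(tr$per_round_best) <= 0))
  expect_equal(length(tr$top100), 100)
  expect_true(!is.unsorted(tr$top100))
  expect_equal(nrow(tr$evaluations), 500)
  expect_error(optimize_parameters("sptl", target$adj, d,
                                   bounds = list(eta = c(-1, -1))),
               "degenerate")
})

test_that("transcriptional constraints improve degree-topography recovery (TG beats ST)", {
  fx <- genetic_target_fixture()
  rho_tg <- rho_st <- numeric(20)
  for (r in 1:20) {
    tg <- optimize_parameters("TG", fx$conn$mask, fx$sim$distances,
                              n_per_round = 10, n_rounds = 2,
                              gexp = fx$gres, seed = 300 + r)
    st <- optimize_parameters("ST", fx$conn$mask, fx$sim$distances,
                              n_per_round = 10, n_rounds = 2, seed = 300 + r)
    rho_tg[r] <- tg$best$degseq_rho
    rho_st[r] <- st$best$degseq_rho
  }
  expect_gt(median(rho_tg), median(rho_st))
})

test_that("genetic variants use the documented factor structure", {
  fx <- genetic_target_fixture()
  d <- fx$sim$distances
  adj <- matrix(0, nrow(d), ncol(d))
  gs <- connherit:::rescale_gexp(fx$gres, 1e-5)
  # G: probabilities proportional to g_hat^lambda over absent pairs
  ws <- wiring_scores(adj, d, "G", lambda = 3, gexp = fx$gres)
  expected <- gs[cbind(ws$candidates$i, ws$candidates$j)]^3
  expect_equal(ws$candidates$p, expected / sum(expected), tolerance = 1e-10)
  # S ignores gamma/lambda: pure distance
  ws_s <- wiring_scores(adj, d, "S", eta = -2)
  dv <- d[cbind(ws_s$candidates$i, ws_s$candidates$j)]
  expect_equal(ws_s$candidates$p, dv^-2 / sum(dv^-2), tolerance = 1e-10)
  # SG combines both
  ws_sg <- wiring_scores(adj, d, "SG", eta = -2, lambda = 3, gexp = fx$gres)
  th <- dv^-2 * expected
  expect_equal(ws_sg$candidates$p, th / sum(th), tolerance = 1e-10)
})
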