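test_that("group thresholding enforces consistency and density rules", {
  # consistency rule: an edge present in 1 of 10 subjects is excluded even
  # with the largest weight
  n <- 8
  base <- matrix(0, n, n)
  base[1, 2] <- base[2, 1] <- 5
  base[3, 4] <- base[4, 3] <- 4
  subs <- replicate(10, base, simplify = FALSE)
  rare <- matrix(0, n, n); rare[5, 6] <- rare[6, 5] <- 100
  subs[[1]] <- subs[[1]] + rare
  conn <- suppressWarnings(
    build_group_connectome(subs, consistency_min = 0.30, density_target = 1))
  expect_equal(conn$mask[5, 6], 0L)
  expect_equal(conn$mask[1, 2], 1L)

  # tau = 1 with no consistency filter keeps the union of subject masks
  # (density 1 is of course unreachable from so few observed edges)
  conn_all <- suppressWarnings(
    build_group_connectome(subs, consistency_min = 0, density_target = 1))
  union_mask <- (Reduce(`+`, lapply(subs, function(m) (m > 0) * 1)) > 0) * 1
  expect_equal(conn_all$mask, union_mask * 1L)

  # density rule: retained count equals round(tau * n(n-1)/2) when enough
  # consistent candidates exist
  set.seed(1)
  m <- matrix(0, 20, 20); ut <- upper.tri(m)
  m[ut] <- rlnorm(sum(ut)); m <- m + t(m)
  conn20 <- build_group_connectome(list(m, m, m), 0.3, 0.25)
  expect_equal(sum(conn20$mask) / 2, round(0.25 * 20 * 19 / 2))
  # group weight equals the cross-subject statistic (here the shared value)
  expect_equal(conn20$weights[conn20$mask > 0], m[conn20$mask > 0])

  expect_error(build_group_connectome(list(matrix(1:4, 2))), "symmetric")
})

test_that("thresholding is deterministic under weight ties", {
  n <- 10
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- 1                     # all weights tie
  m <- m + t(m)
  c1 <- build_group_connectome(list(m), 0, 0.2)
  c2 <- build_group_connectome(list(m), 0, 0.2)
  expect_identical(c1$mask, c2$mask)
  # lowest node-index pairs win the tie-break
  ed <- connectome_edges(c1)
  expect_equal(ed$i[1], 1)
})

test_that("link classification partitions edges by endpoint hub status", {
  # 5-node star, k = 1: centre is the only hub, all 4 edges are feeders
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  cl <- classify_links(as_connectome(star), k = 1)
  expect_equal(cl$hubs, 1L)
  expect_equal(table(cl$edges$class)[["feeder"]], 4)
  expect_false(any(cl$edges$class %in% c("rich", "peripheral")))

  # class counts always sum to the edge count
  conn <- toy_connectome()
  for (k in 0:6) {
    cl <- classify_links(conn, k)
    expect_equal(nrow(cl$edges), sum(conn$mask) / 2)
  }
  # k = 0 on a connected graph: everything is rich
  full <- as_connectome(matrix(1, 4, 4) - diag(4))
  expect_true(all(classify_links(full, 0)$edges$class == "rich"))
})

test_that("rich-club coefficients match enumeration on canonical graphs", {
  k4 <- matrix(1, 4, 4) - diag(4)
  expect_equal(rich_club_coefficient(k4, 2), 1)
  # path P4 at k = 1: the two middle nodes form a connected subgraph
  p4 <- matrix(0, 4, 4)
  p4[cbind(1:3, 2:4)] <- 1; p4 <- p4 + t(p4)
  expect_equal(rich_club_coefficient(p4, 1), 1)
  # k at the maximum degree: undefined
  expect_true(is.na(rich_club_coefficient(p4, 2)))

  # uniform weights: phi_w = 1 wherever defined
  cw <- as_connectome(p4 * 1)
  expect_equal(weighted_rich_club_coefficient(cw, 1), 1)
})

test_that("phi and phi_w agree with brute-force enumeration on all graphs up to 5 nodes", {
  set.seed(4)
  for (n in 3:5) {
    graphs <- all_graphs(n)
    for (a in graphs) {
      if (sum(a) == 0) next
      w <- a * matrix(runif(n * n, 0.5, 2), n, n)
      w[lower.tri(w)] <- t(w)[lower.tri(w)]
      conn <- as_connectome(w)
      for (k in 0:(n - 2)) {
        expect_equal(rich_club_coefficient(conn, k), oracle_phi(a, k))
        expect_equal(weighted_rich_club_coefficient(conn, k),
                     oracle_phiw(w, k))
      }
    }
  }
})

test_that("phi and phi_w match enumeration on sampled 6-node graphs", {
  set.seed(5)
  for (rep in 1:300) {
    a <- matrix(0, 6, 6)
    ut <- upper.tri(a)
    a[ut] <- rbinom(sum(ut), 1, runif(1, 0.2, 0.8))
    a <- a + t(a)
    if (sum(a) == 0) next
    w <- a * matrix(runif(36, 0.5, 2), 6, 6)
    w[lower.tri(w)] <- t(w)[lower.tri(w)]
    conn <- as_connectome(w)
    k <- sample(0:4, 1)
    expect_equal(rich_club_coefficient(conn, k), oracle_phi(a, k))
    expect_equal(weighted_rich_club_coefficient(conn, k), oracle_phiw(w, k))
  }
})

test_that("rewiring preserves the degree sequence and simple-graph property", {
  conn <- toy_connectome(20, 0.3, seed = 3)
  null <- degree_preserving_rewire(conn, swaps_per_edge = 20, seed = 1)
  expect_equal(rowSums(null), rowSums(conn$mask))
  expect_true(all(diag(null) == 0))
  expect_true(all(null %in% c(0, 1)))
  expect_equal(sum(null) / 2, sum(conn$mask) / 2)
  # K3 admits no valid swap: output equals input
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(degree_preserving_rewire(k3, seed = 1), k3)
})

test_that("weight-permutation null keeps topology; uniform weights give Phi_norm = 1", {
  conn <- toy_connectome(15, 0.5, seed = 9)
  uni <- as_connectome((conn$mask > 0) * 1)
  rc <- normalized_rich_club_curve(uni, n_null = 20, mode = "weighted",
                                   seed = 2)
  defined <- is.finite(rc$phi_norm)
  expect_true(any(defined))
  expect_equal(rc$phi_norm[defined], rep(1, sum(defined)))
  # p never reaches 0 under the add-one rule
  rcb <- normalized_rich_club_curve(conn, n_null = 25, seed = 3)
  expect_true(all(rcb$p[is.finite(rcb$p)] > 0))
  expect_true(all(rcb$p[is.finite(rcb$p)] <= 1))
})

test_that("planted rich club is detected against rewired nulls", {
  fx <- richclub_fixture()
  rc <- normalized_rich_club_curve(fx$conn, k_grid = fx$planted_k,
                                   n_null = 100, seed = 9)
  expect_true(all(rc$phi_norm > 1))
  expect_true(all(rc$p < 0.05))
})

test_that("communicability matches closed forms and the truncated series", {
  # single edge: cosh/sinh
  e2 <- matrix(c(0, 1, 1, 0), 2)
  cm <- communicability(e2, "binary")
  expect_equal(cm[1, 2], sinh(1), tolerance = 1e-9)
  expect_equal(cm[1, 1], cosh(1), tolerance = 1e-9)
  # K3 off-diagonal from the eigendecomposition: (e^2 - e^-1) / 3
  k3 <- matrix(1, 3, 3) - diag(3)
  expect_equal(communicability(k3, "binary")[1, 2], (exp(2) - exp(-1)) / 3,
               tolerance = 1e-9)
  # empty graph: identity
  expect_equal(communicability(matrix(0, 4, 4), "binary"), diag(4))
  # strength normalization cancels on a 2-node weighted graph
  for (w in c(0.2, 1, 7.3, 40)) {
    m <- matrix(c(0, w, w, 0), 2)
    expect_equal(communicability(m, "weighted")[1, 2], sinh(1),
                 tolerance = 1e-9)
  }
  # truncated power-series oracle on random graphs with spectral radius <= 3
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    a <- matrix(0, n, n); ut <- upper.tri(a)
    a[ut] <- rbinom(sum(ut), 1, 0.3); a <- a + t(a)
    if (max(abs(eigen(a, only.values = TRUE)$values)) > 3) next
    expect_equal(communicability(a, "binary"),
                 oracle_communicability_series(a, 20), tolerance = 1e-9)
  }
  # isolated node in weighted mode: identity contribution, with warning
  iso <- matrix(0, 3, 3); iso[1, 2] <- iso[2, 1] <- 2
  expect_warning(cw <- communicability(iso, "weighted"), "isolated")
  expect_equal(cw[3, 3], 1)
  expect_equal(cw[3, 1], 0)
})

test_that("link-type curves report class means, SEMs and one-sided Welch tests", {
  conn <- toy_connectome(20, 0.4, seed = 5)
  ed <- connectome_edges(conn)
  m <- nrow(ed)

  # identical values: t = 0, one-sided p = 0.5 for every testable class
  flat <- link_type_curve(conn, rep(1, m), k_grid = c(2, 4))
  tested <- !is.na(flat$t)
  expect_true(all(flat$t[tested] == 0))
  expect_true(all(flat$p[tested] == 0.5))

  # class means weighted-average to the global mean
  set.seed(6)
  v <- rnorm(m)
  curve <- link_type_curve(conn, v, k_grid = 3)
  got <- curve[!is.na(curve$mean), ]
  expect_equal(sum(got$mean * got$n) / sum(got$n), mean(v), tolerance = 1e-12)
  expect_true(all(got$sem >= 0, na.rm = TRUE))

  # boosted rich links are detected at the planted thresholds
  fx <- richclub_fixture()
  edf <- connectome_edges(fx$conn)
  hub <- seq_len(nrow(fx$conn$mask)) %in% fx$hubs
  vals <- rnorm(nrow(edf), 0, 0.5) + ifelse(hub[edf$i] & hub[edf$j], 1, 0)
  cur <- link_type_curve(fx$conn, vals, k_grid = fx$planted_k)
  rich <- cur[cur$class == "rich", ]
  expect_true(all(rich$p < 0.05))
})
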