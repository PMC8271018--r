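test_that("generator specs validate their invariants", {
  expect_error(cohort_spec(n_nodes = 5), "n_nodes")
  expect_error(cohort_spec(hub_fraction = 0), "hub_fraction")
  expect_error(cohort_spec(decay_scale = -1), "decay_scale")
  expect_error(twin_spec(a2 = -0.1, e2 = 1.1), "nonnegative")
  expect_error(twin_spec(a2 = 0.5, c2 = 0.5, t2 = 0.5, e2 = 0.5), "equal 1")
  expect_error(expression_spec(n_genes = 1), "n_genes")
  expect_error(expression_spec(n = 0), "positive")
  expect_error(simulate_cell_type_profiles(marker_fraction = 1.2),
               "marker_fraction")
  expect_error(simulate_intensity_profiles(n_surfaces = 1), "n_surfaces")
})

test_that("every generator is bit-identical under a fixed seed", {
  sp <- cohort_spec(n_nodes = 20, n_subjects = 3, seed = 42)
  expect_identical(simulate_cohort_connectomes(sp),
                   simulate_cohort_connectomes(sp))
  tsp <- twin_spec(n_mz_pairs = 10, n_dz_pairs = 10, n_mz_sibs = 2,
                   n_dz_sibs = 2, seed = 42)
  expect_identical(simulate_twin_cohort(tsp, 3), simulate_twin_cohort(tsp, 3))
  sim <- simulate_cohort_connectomes(sp)
  esp <- expression_spec(n_genes = 20, seed = 42)
  expect_identical(simulate_expression(esp, sim$nodes, sim$hubs),
                   simulate_expression(esp, sim$nodes, sim$hubs))
  expect_identical(simulate_cell_type_profiles(seed = 42),
                   simulate_cell_type_profiles(seed = 42))
  expect_identical(simulate_intensity_profiles(seed = 42),
                   simulate_intensity_profiles(seed = 42))
})

test_that("subject connectomes are symmetric, nonnegative, hollow, with both weight channels", {
  sim <- simulate_cohort_connectomes(
    cohort_spec(n_nodes = 30, n_subjects = 4, seed = 1))
  for (s in sim$subjects) {
    for (ch in c("sc", "fa")) {
      m <- s[[ch]]
      expect_equal(m, t(m))
      expect_true(all(diag(m) == 0))
      expect_true(all(m >= 0))
    }
    fa_vals <- s$fa[s$fa > 0]
    expect_true(all(fa_vals > 0 & fa_vals < 1))
  }
})

test_that("boost-free infinite-decay cohort is Erdos-Renyi (binomial degree law)", {
  spec <- cohort_spec(n_nodes = 100, n_subjects = 4, hub_fraction = 0.1,
                      richclub_boost = 0, base_prob = 0.3,
                      decay_scale = 1e9, seed = 2)
  sim <- simulate_cohort_connectomes(spec)
  expect_equal(max(abs(sim$presence_prob[upper.tri(sim$presence_prob)] - 0.3)),
               0, tolerance = 1e-6)
  deg <- unlist(lapply(sim$subjects, function(s) rowSums(s$sc > 0)))
  expect_gt(oracle_binom_gof(deg, 100, 0.3), 0.01)
})

test_that("planted hubs occupy the top decile of expected and realized degree", {
  spec <- cohort_spec(n_nodes = 100, n_subjects = 20, hub_fraction = 0.1,
                      richclub_boost = 0.8, hub_degree_boost = 0.3, seed = 5)
  sim <- simulate_cohort_connectomes(spec)
  top <- ceiling(0.1 * 100)
  expect_true(all(rank(-sim$expected_degree)[sim$hubs] <= top))
  mean_deg <- Reduce(`+`, lapply(sim$subjects, function(s) rowSums(s$sc > 0)))
  expect_true(all(rank(-mean_deg)[sim$hubs] <= top + 2))
})

test_that("twin phenotype correlations match the closed-form sharing model", {
  # large cohort of pairs; expectations: rMZ = a2+c2+t2, rDZ = .5 a2+c2+t2
  sp <- twin_spec(n_mz_pairs = 10000, n_dz_pairs = 10000, n_mz_sibs = 0,
                  n_dz_sibs = 0, a2 = 0.5, c2 = 0.2, t2 = 0.1, e2 = 0.2,
                  beta_age = 0, beta_sex = 0, seed = 7)
  tw <- simulate_twin_cohort(sp, 1)
  s <- tw$subjects
  y <- tw$phenotypes[, 1]
  t1 <- y[s$role == "twin1"]; t2 <- y[s$role == "twin2"]
  zyg <- s$zygosity[s$role == "twin1"]
  expect_equal(cor(t1[zyg == "MZ"], t2[zyg == "MZ"]), 0.8, tolerance = 0.03)
  expect_equal(cor(t1[zyg == "DZ"], t2[zyg == "DZ"]), 0.55, tolerance = 0.03)

  # pure-A and pure-E corners
  spA <- twin_spec(n_mz_pairs = 5000, n_dz_pairs = 5000, n_mz_sibs = 0,
                   n_dz_sibs = 0, a2 = 1, c2 = 0, t2 = 0, e2 = 0,
                   beta_age = 0, beta_sex = 0, seed = 8)
  yA <- simulate_twin_cohort(spA, 1)
  sA <- yA$subjects; vA <- yA$phenotypes[, 1]
  z <- sA$zygosity[sA$role == "twin1"]
  r1 <- vA[sA$role == "twin1"]; r2 <- vA[sA$role == "twin2"]
  expect_equal(cor(r1[z == "MZ"], r2[z == "MZ"]), 1, tolerance = 1e-8)
  expect_equal(cor(r1[z == "DZ"], r2[z == "DZ"]), 0.5, tolerance = 0.04)
  spE <- twin_spec(n_mz_pairs = 5000, n_dz_pairs = 5000, n_mz_sibs = 0,
                   n_dz_sibs = 0, a2 = 0, c2 = 0, t2 = 0, e2 = 1,
                   beta_age = 0, beta_sex = 0, seed = 9)
  yE <- simulate_twin_cohort(spE, 1)
  sE <- yE$subjects; vE <- yE$phenotypes[, 1]
  zE <- sE$zygosity[sE$role == "twin1"]
  expect_lt(abs(cor(vE[sE$role == "twin1"][zE == "MZ"],
                    vE[sE$role == "twin2"][zE == "MZ"])), 0.05)
})

test_that("twin-sibling covariance converges to 0.5 a2 + c2", {
  sp <- twin_spec(n_mz_pairs = 8000, n_dz_pairs = 0, n_mz_sibs = 8000,
                  n_dz_sibs = 0, a2 = 0.6, c2 = 0.2, t2 = 0.1, e2 = 0.1,
                  beta_age = 0, beta_sex = 0, seed = 11)
  tw <- simulate_twin_cohort(sp, 1)
  s <- tw$subjects; y <- tw$phenotypes[, 1]
  tw1 <- y[s$role == "twin1"]; sib <- y[s$role == "sibling"]
  expect_equal(cov(tw1, sib), 0.5 * 0.6 + 0.2, tolerance = 0.04)
})

test_that("expression generator plants the decay and the hub-coupling boost", {
  sim <- simulate_cohort_connectomes(cohort_spec(n_nodes = 60, seed = 21))
  es0 <- expression_spec(n_genes = 3000, noise_sd = 0,
                         hub_coupling_boost = 0, seed = 22)
  ex0 <- simulate_expression(es0, sim$nodes)
  fit <- fit_distance_decay(cge_matrix(ex0$expr), ex0$distances)
  # refit oracle: generator parameters recovered from the empirical CGE
  expect_equal(fit$A, es0$A, tolerance = 0.08)
  expect_equal(fit$B, es0$B, tolerance = 0.05)
  expect_equal(fit$n, es0$n, tolerance = 15)

  esb <- expression_spec(n_genes = 800, hub_coupling_boost = 0.3, seed = 23)
  exb <- simulate_expression(esb, sim$nodes, sim$hubs)
  res <- cge_matrix(exb$expr) - (esb$A * exp(-exb$distances / esb$n) + esb$B)
  hub <- seq_len(60) %in% sim$hubs
  hh <- outer(hub, hub, `&`) & upper.tri(res)
  other <- !outer(hub, hub, `&`) & upper.tri(res)
  expect_gt(mean(res[hh]), mean(res[other]) + 0.1)
})

test_that("a non-positive-definite implied covariance is repaired with a warning", {
  sim <- simulate_cohort_connectomes(cohort_spec(n_nodes = 40, seed = 2))
  es <- expression_spec(n_genes = 50, hub_coupling_boost = 2, seed = 3)
  expect_warning(ex <- simulate_expression(es, sim$nodes, sim$hubs),
                 "positive definite")
  cge <- cge_matrix(ex$expr)
  expect_true(all(abs(cge[is.finite(cge)]) <= 1 + 1e-12))
})

test_that("two-gene atlas still yields a valid CGE matrix", {
  sim <- simulate_cohort_connectomes(cohort_spec(n_nodes = 15, seed = 1))
  ex <- simulate_expression(expression_spec(n_genes = 3, seed = 2),
                            sim$nodes)
  cge <- cge_matrix(ex$expr)
  expect_equal(cge, t(cge))
  expect_true(all(abs(cge[is.finite(cge)]) <= 1 + 1e-12))
})

test_that("planted cell-type markers satisfy the level and fold rule, non-markers fail it", {
  ct <- simulate_cell_type_profiles(n_genes = 150, n_classes = 6,
                                    marker_fraction = 0.25, seed = 3)
  called <- derive_cell_markers(ct$profiles, level_min = 5, fold_min = 4)
  expect_identical(called$class, ct$truth$class)
  expect_true(attr(simulate_cell_type_profiles(n_classes = 1, seed = 1),
                   "degenerate"))
})

test_that("intensity profiles share block templates and a removable y trend", {
  pr <- simulate_intensity_profiles(n_regions = 60, n_blocks = 4, seed = 2)
  expect_equal(ncol(pr$profiles), 16)
  res <- residualize_profiles(pr$profiles, pr$y)
  # regression oracle: y-trend removal leaves every depth uncorrelated with y
  expect_lt(max(abs(apply(res, 2, cor, pr$y))), 1e-10)
  mp <- mpc_matrix(res)
  same <- outer(pr$blocks, pr$blocks, `==`)
  ut <- upper.tri(same)
  expect_gt(mean(mp$mpc[same & ut], na.rm = TRUE),
            mean(mp$mpc[!same & ut], na.rm = TRUE))
})
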