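# Synthetic-data generators. These emulate the statistical structure of the
# real inputs (twin-imaging connectomes, transcriptomic atlas, depth-wise
# histology) so every downstream analysis can be exercised without any
# external download: geometric connectomes with planted, spatially
# distributed hubs; twin phenotypes with specified A/C/T/E variance
# fractions; expression with exponential distance-decay of coupling plus
# elevated hub-hub coupling; and depth-wise intensity profiles with block
# cytoarchitectonic similarity.

#' Specification for a synthetic imaging cohort
#'
#' @param n_nodes number of brain regions (nodes); at least 10.
#' @param n_subjects number of subjects.
#' @param hub_fraction fraction of nodes planted as hubs, in (0, 1).
#' @param richclub_boost extra connection probability between planted hubs
#'   (additive on the geometric baseline).
#' @param hub_degree_boost extra connection probability between a hub and a
#'   nonhub. Defaults to a third of `richclub_boost` so planted hubs are
#'   high-degree overall, as real connectome hubs are, not merely densely
#'   inter-connected.
#' @param base_prob connection probability at zero distance.
#' @param decay_scale length scale (mm) of the exponential distance decay of
#'   connection probability.
#' @param weight_noise_sd subject-level noise SD applied to edge weights
#'   (log scale for SC-like weights, logit scale for FA-like weights).
#' @param box side lengths (mm) of the box node coordinates are drawn in.
#' @param n_modules number of functional-module labels to assign.
#' @param seed integer seed; recorded in the output.
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nodes = 100, n_subjects = 50, hub_fraction = 0.12,
                        richclub_boost = 0.4,
                        hub_degree_boost = richclub_boost / 3,
                        base_prob = 0.8, decay_scale = 60,
                        weight_noise_sd = 0.1,
                        box = c(140, 170, 120), n_modules = 6, seed = 1L) {
  if (n_nodes < 10) stop_param("n_nodes must be >= 10")
  if (!(hub_fraction > 0 && hub_fraction < 1))
    stop_param("hub_fraction must lie strictly between 0 and 1")
  if (decay_scale <= 0) stop_param("decay_scale must be positive")
  if (richclub_boost < 0 || hub_degree_boost < 0)
    stop_param("connection-probability boosts must be nonnegative")
  if (weight_noise_sd < 0) stop_param("weight_noise_sd must be nonnegative")
  if (base_prob <= 0 || base_prob > 1)
    stop_param("base_prob must lie in (0, 1]")
  structure(list(n_nodes = as.integer(n_nodes),
                 n_subjects = as.integer(n_subjects),
                 hub_fraction = hub_fraction,
                 richclub_boost = richclub_boost,
                 hub_degree_boost = hub_degree_boost,
                 base_prob = base_prob, decay_scale = decay_scale,
                 weight_noise_sd = weight_noise_sd, box = box,
                 n_modules = as.integer(n_modules), seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a cohort of weighted connectomes with planted hubs
#'
#' Nodes get uniform 3-D coordinates in a box; an edge between regions i and
#' j is present in a subject with probability
#' `base_prob * exp(-d_ij / decay_scale)`, plus `richclub_boost` if both
#' endpoints are planted hubs and `hub_degree_boost` if exactly one is
#' (probabilities truncated at 1). Planted hubs are sampled across modules so
#' they are spatially distributed. Two weight channels are generated for
#' present edges: a heavy-tailed streamline-count-like channel (log-normal,
#' decaying with distance) and a bounded (0, 1) FA-like channel.
#'
#' @param spec a [cohort_spec()].
#' @return A list with elements `nodes` (data.frame: id, x, y, z, module,
#'   hemisphere, hub), `hubs` (integer node ids), `subjects` (list, one per
#'   subject, each with `sc` and `fa` matrices), `presence_prob` (the n x n
#'   edge-presence probability matrix), `expected_degree`, `distances`, and
#'   `spec`.
#' @export
simulate_cohort_connectomes <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_nodes
  coords <- cbind(x = runif(n, 0, spec$box[1]),
                  y = runif(n, 0, spec$box[2]),
                  z = runif(n, 0, spec$box[3]))
  d <- coord_dist(coords)
  hemisphere <- ifelse(coords[, "x"] < spec$box[1] / 2, "L", "R")
  km <- suppressWarnings(
    stats::kmeans(coords, centers = min(spec$n_modules, n), nstart = 5))
  module <- paste0("M", km$cluster)

  n_hubs <- max(2L, round(spec$hub_fraction * n))
  # spread planted hubs across modules: sample proportionally per module
  hub_pool <- split(seq_len(n), module)
  hubs <- integer(0)
  while (length(hubs) < n_hubs) {
    for (g in hub_pool) {
      g <- setdiff(g, hubs)
      if (length(g) && length(hubs) < n_hubs)
        hubs <- c(hubs, if (length(g) == 1) g else sample(g, 1))
    }
  }
  hubs <- sort(hubs[seq_len(n_hubs)])

  is_hub <- seq_len(n) %in% hubs
  p <- spec$base_prob * exp(-d / spec$decay_scale)
  p <- p + spec$richclub_boost * outer(is_hub, is_hub, `&`)
  p <- p + spec$hub_degree_boost * outer(is_hub, is_hub, xor)
  p <- pmin(p, 1)
  diag(p) <- 0

  # latent edge-level weight parameters (shared across subjects)
  pairs <- upper_pairs(n)
  dv <- d[pairs]
  m_pairs <- nrow(pairs)
  hub_pair <- outer(is_hub, is_hub, `&`)[pairs]
  feeder_pair <- outer(is_hub, is_hub, xor)[pairs]
  # hub-involved edges carry systematically stronger weights (the planted
  # rich-club backbone), scaled by the same boost parameters
  sc_meanlog <- log(150) - dv / (2 * spec$decay_scale) +
    2 * spec$richclub_boost * hub_pair +
    2 * spec$hub_degree_boost * feeder_pair +
    rnorm(m_pairs, 0, 0.3)
  fa_logit <- rnorm(m_pairs, 0, 0.5)
  pv <- p[pairs]

  subjects <- vector("list", spec$n_subjects)
  for (s in seq_len(spec$n_subjects)) {
    present <- runif(m_pairs) < pv
    sc <- numeric(m_pairs)
    fa <- numeric(m_pairs)
    np <- sum(present)
    if (np) {
      sc[present] <- rlnorm(np, sc_meanlog[present],
                            0.4 + spec$weight_noise_sd)
      fa[present] <- plogis(fa_logit[present] +
                              rnorm(np, 0, 0.5 + spec$weight_noise_sd))
    }
    subjects[[s]] <- list(sc = sym_from_upper(sc, n),
                          fa = sym_from_upper(fa, n))
  }

  nodes <- data.frame(id = seq_len(n) - 1L,
                      x = coords[, 1], y = coords[, 2], z = coords[, 3],
                      module = module, hemisphere = hemisphere,
                      hub = is_hub)
  list(nodes = nodes, hubs = hubs, subjects = subjects,
       presence_prob = p, expected_degree = rowSums(p),
       distances = d, spec = spec)
}

#' Specification for a synthetic twin cohort
#'
#' Default family counts follow the twin-imaging cohort structure used
#' throughout the package: 117 MZ twin pairs with 69 non-twin siblings and
#' 60 DZ twin pairs with 48 non-twin siblings.
#'
#' @param n_mz_pairs,n_dz_pairs numbers of MZ / DZ twin pairs.
#' @param n_mz_sibs,n_dz_sibs numbers of MZ / DZ families that additionally
#'   contribute one non-twin sibling (must not exceed the pair counts).
#' @param a2,c2,t2,e2 variance fractions for additive genetic, twin
#'   non-specific common environment, twin-specific common environment and
#'   unique environment. Each may be a scalar or a per-edge vector; per edge
#'   they must be nonnegative and sum to 1.
#' @param beta_age,beta_sex linear covariate effects added to the phenotype
#'   mean (per year of age; for sex coded 0/1).
#' @param mean_age,sd_age cohort age distribution (years).
#' @param seed integer seed.
#' @return An object of class `twin_spec`.
#' @export
twin_spec <- function(n_mz_pairs = 117, n_dz_pairs = 60,
                      n_mz_sibs = 69, n_dz_sibs = 48,
                      a2 = 0.5, c2 = 0.1, t2 = 0.1, e2 = 0.3,
                      beta_age = 0.01, beta_sex = 0.1,
                      mean_age = 29, sd_age = 3.5, seed = 1L) {
  fr <- cbind(a2, c2, t2, e2)
  if (any(fr < 0)) stop_param("variance fractions must be nonnegative")
  if (any(abs(rowSums(fr) - 1) > 1e-8))
    stop_param("a2 + c2 + t2 + e2 must equal 1 for every edge")
  if (n_mz_sibs > n_mz_pairs || n_dz_sibs > n_dz_pairs)
    stop_param("sibling counts cannot exceed the corresponding pair counts")
  structure(list(n_mz_pairs = as.integer(n_mz_pairs),
                 n_dz_pairs = as.integer(n_dz_pairs),
                 n_mz_sibs = as.integer(n_mz_sibs),
                 n_dz_sibs = as.integer(n_dz_sibs),
                 a2 = a2, c2 = c2, t2 = t2, e2 = e2,
                 beta_age = beta_age, beta_sex = beta_sex,
                 mean_age = mean_age, sd_age = sd_age,
                 seed = as.integer(seed)),
            class = "twin_spec")
}

#' Simulate edge phenotypes for a twin-plus-sibling cohort
#'
#' Each family member's phenotype is the sum of four latent factors scaled by
#' the square-root variance fractions, plus linear age and sex effects:
#' * A (additive genetic): MZ twins share the factor fully; DZ twins and any
#'   twin--sibling pair share it with coefficient 0.5, constructed as
#'   `sqrt(0.5) * family-shared + sqrt(0.5) * individual` (for MZ families
#'   the twin-pair part is itself shared so the twins correlate 1).
#' * C (common environment): shared by all family members.
#' * T (twin-specific common environment): shared by the two twins; the
#'   sibling draws an independent copy, so every member has total variance
#'   `a2 + c2 + t2 + e2 = 1` while the twin--sibling covariance is
#'   `0.5 a2 + c2`.
#' * E (unique environment): independent per member.
#'
#' @param spec a [twin_spec()].
#' @param n_edges number of edge phenotypes to simulate.
#' @return A `family_cohort`: list with `subjects` (data.frame: subject_id,
#'   family_id, zygosity, role, age, sex) and `phenotypes` (subjects x edges
#'   matrix, columns named `e<j>`), plus the generating `spec`.
#' @export
simulate_twin_cohort <- function(spec, n_edges = 1L) {
  stopifnot(inherits(spec, "twin_spec"))
  set.seed(spec$seed)
  expand <- function(x) rep_len(x, n_edges)
  a <- sqrt(expand(spec$a2)); cc <- sqrt(expand(spec$c2))
  tt <- sqrt(expand(spec$t2)); e <- sqrt(expand(spec$e2))

  fam_rows <- function(fid, zyg, with_sib) {
    roles <- c("twin1", "twin2", if (with_sib) "sibling")
    data.frame(family_id = fid, zygosity = zyg, role = roles,
               stringsAsFactors = FALSE)
  }
  fams <- list()
  fid <- 0L
  for (i in seq_len(spec$n_mz_pairs)) {
    fid <- fid + 1L
    fams[[fid]] <- fam_rows(fid, "MZ", i <= spec$n_mz_sibs)
  }
  for (i in seq_len(spec$n_dz_pairs)) {
    fid <- fid + 1L
    fams[[fid]] <- fam_rows(fid, "DZ", i <= spec$n_dz_sibs)
  }
  subjects <- do.call(rbind, fams)
  n_sub <- nrow(subjects)
  subjects$subject_id <- sprintf("S%04d", seq_len(n_sub))
  fam_age <- rnorm(fid, spec$mean_age, spec$sd_age)
  subjects$age <- fam_age[subjects$family_id] +
    ifelse(subjects$role == "sibling", rnorm(n_sub, 0, 2), 0)
  # twins in a pair share sex (DZ pairs in the emulated cohort are same-sex)
  fam_sex <- rbinom(fid, 1, 0.5)
  subjects$sex <- ifelse(subjects$role == "sibling",
                         rbinom(n_sub, 1, 0.5), fam_sex[subjects$family_id])

  pheno <- matrix(NA_real_, n_sub, n_edges,
                  dimnames = list(subjects$subject_id,
                                  paste0("e", seq_len(n_edges))))
  is_twin <- subjects$role != "sibling"
  for (f in seq_len(fid)) {
    rows <- which(subjects$family_id == f)
    mz <- subjects$zygosity[rows[1]] == "MZ"
    m <- length(rows)
    A_fam <- rnorm(n_edges)
    A_pair <- rnorm(n_edges)            # shared by MZ twins
    C_fam <- rnorm(n_edges)
    T_twin <- rnorm(n_edges)            # shared by the two twins
    for (r in rows) {
      if (is_twin[r]) {
        A_ind <- if (mz) A_pair else rnorm(n_edges)
        T_r <- T_twin
      } else {
        A_ind <- rnorm(n_edges)
        T_r <- rnorm(n_edges)
      }
      A_r <- sqrt(0.5) * A_fam + sqrt(0.5) * A_ind
      val <- a * A_r + cc * C_fam + tt * T_r + e * rnorm(n_edges) +
        spec$beta_age * subjects$age[r] + spec$beta_sex * subjects$sex[r]
      pheno[r, ] <- val
    }
  }
  structure(list(subjects = subjects[, c("subject_id", "family_id",
                                         "zygosity", "role", "age", "sex")],
                 phenotypes = pheno, spec = spec),
            class = "family_cohort")
}

#' Specification for a synthetic expression atlas
#'
#' Defaults for the distance-decay of correlated gene expression follow the
#' exponential trend `r(d) = A * exp(-d / n) + B` with A = 0.64, B = -0.19
#' and n = 90.4 mm.
#'
#' @param n_genes number of genes (>= 2).
#' @param A,B,n decay amplitude, offset and length scale (mm); `n > 0`.
#' @param hub_coupling_boost additive boost to the target coupling of
#'   hub-hub region pairs.
#' @param noise_sd additive expression noise SD.
#' @param n_cell_classes number of cell classes genes are annotated with.
#' @param seed integer seed.
#' @return An object of class `expression_spec`.
#' @export
expression_spec <- function(n_genes = 500, A = 0.64, B = -0.19, n = 90.4,
                            hub_coupling_boost = 0.15, noise_sd = 0.05,
                            n_cell_classes = 7, seed = 1L) {
  if (n_genes < 2) stop_param("n_genes must be >= 2")
  if (n <= 0) stop_param("decay scale n must be positive")
  if (hub_coupling_boost < 0 || noise_sd < 0)
    stop_param("hub_coupling_boost and noise_sd must be nonnegative")
  structure(list(n_genes = as.integer(n_genes), A = A, B = B, n = n,
                 hub_coupling_boost = hub_coupling_boost,
                 noise_sd = noise_sd,
                 n_cell_classes = as.integer(n_cell_classes),
                 seed = as.integer(seed)),
            class = "expression_spec")
}

#' Simulate a region-by-gene expression table with planted coupling structure
#'
#' Uses a latent-covariance construction: a target region-level correlation
#' matrix is assembled as `A * exp(-d_ij / n) + B`, plus
#' `hub_coupling_boost` on hub-hub pairs, and each gene's spatial profile is
#' drawn from a multivariate normal with that correlation. In expectation the
#' correlated gene expression (CGE) of the generated table therefore follows
#' the planted decay exactly. If the implied matrix is not positive definite
#' it is repaired by minimal diagonal inflation (with a warning) and
#' rescaled back to a correlation.
#'
#' @param spec an [expression_spec()].
#' @param nodes node table with columns x, y, z (e.g. from
#'   [simulate_cohort_connectomes()]), or an n x 3 coordinate matrix.
#' @param hubs integer indices (1-based) of the hub regions.
#' @return A list with `expr` (regions x genes matrix), `gene_classes`
#'   (data.frame: gene, class), `cge_target` (the exact planted region
#'   correlation matrix, useful for noiseless refits), `distances`, and
#'   `spec`.
#' @export
simulate_expression <- function(spec, nodes, hubs = integer(0)) {
  stopifnot(inherits(spec, "expression_spec"))
  coords <- if (is.data.frame(nodes)) as.matrix(nodes[, c("x", "y", "z")])
            else as.matrix(nodes)
  if (anyNA(coords)) stop_param("coordinates must be available for all regions")
  set.seed(spec$seed)
  n_reg <- nrow(coords)
  d <- coord_dist(coords)
  sigma <- spec$A * exp(-d / spec$n) + spec$B
  if (length(hubs)) {
    is_hub <- seq_len(n_reg) %in% hubs
    sigma <- sigma + spec$hub_coupling_boost * outer(is_hub, is_hub, `&`)
  }
  sigma <- pmin(sigma, 0.99)
  diag(sigma) <- 1
  target <- sigma
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8) {
    infl <- abs(min(ev)) + 1e-6
    warning(sprintf(paste("implied region covariance not positive definite;",
                          "inflating diagonal by %.3g"), infl))
    diag(sigma) <- diag(sigma) + infl
    sigma <- stats::cov2cor(sigma)
  }
  g <- MASS::mvrnorm(spec$n_genes, mu = rep(0, n_reg), Sigma = sigma)
  expr <- t(g)                                    # regions x genes
  if (spec$noise_sd > 0)
    expr <- expr + rnorm(length(expr), 0, spec$noise_sd)
  dimnames(expr) <- list(paste0("R", seq_len(n_reg) - 1L),
                         paste0("g", seq_len(spec$n_genes)))
  classes <- paste0("class", sample.int(spec$n_cell_classes,
                                        spec$n_genes, replace = TRUE))
  list(expr = expr,
       gene_classes = data.frame(gene = colnames(expr), class = classes,
                                 stringsAsFactors = FALSE),
       cge_target = target, distances = d, spec = spec)
}

#' Simulate cell-class expression profiles with planted markers
#'
#' A fixture for marker derivation: planted markers are expressed well above
#' `level` in one class and near zero elsewhere, so they satisfy an
#' expression-level > 5 and four-fold enrichment rule; non-marker genes are
#' expressed comparably across classes and fail it.
#'
#' @param n_genes,n_classes table dimensions.
#' @param marker_fraction fraction of genes planted as markers, in (0, 1).
#' @param level expression level of a marker in its own class.
#' @param seed integer seed.
#' @return A list with `profiles` (classes x genes matrix) and `truth`
#'   (data.frame: gene, class — `"none"` for non-markers). With one class
#'   the table is flagged degenerate via the `degenerate` attribute.
#' @export
simulate_cell_type_profiles <- function(n_genes = 200, n_classes = 7,
                                        marker_fraction = 0.2, level = 20,
                                        seed = 1L) {
  if (!(marker_fraction > 0 && marker_fraction < 1))
    stop_param("marker_fraction must lie strictly between 0 and 1")
  set.seed(seed)
  genes <- paste0("g", seq_len(n_genes))
  cls <- paste0("class", seq_len(n_classes))
  n_mark <- max(1L, round(marker_fraction * n_genes))
  markers <- sample(genes, n_mark)
  marker_class <- sample(cls, n_mark, replace = TRUE)
  prof <- matrix(0, n_classes, n_genes, dimnames = list(cls, genes))
  # non-markers: similar moderate expression everywhere (fold < 2)
  base <- runif(n_genes, 2, 10)
  for (k in seq_len(n_classes))
    prof[k, ] <- base * runif(n_genes, 0.8, 1.2)
  for (m in seq_along(markers)) {
    g <- markers[m]
    prof[, g] <- runif(n_classes, 0.1, level / 8)
    prof[marker_class[m], g] <- level * runif(1, 1, 1.5)
  }
  truth <- data.frame(gene = genes, class = "none", stringsAsFactors = FALSE)
  truth$class[match(markers, truth$gene)] <- marker_class
  out <- list(profiles = prof, truth = truth, seed = seed)
  if (n_classes == 1) attr(out, "degenerate") <- TRUE
  out
}

#' Simulate depth-wise intensity profiles with block structure
#'
#' Regions in the same cytoarchitectonic block share a smooth depth-profile
#' template plus noise; a linear trend in the anterior-posterior (y)
#' coordinate is injected into every depth so that the y-residualization
#' step is exercised.
#'
#' @param n_regions number of regions.
#' @param n_surfaces number of intradepth surfaces (>= 2; default 16).
#' @param n_blocks number of cytoarchitectonic blocks.
#' @param noise_sd profile noise SD.
#' @param y_trend slope of the injected per-unit-y intensity trend.
#' @param seed integer seed.
#' @return A list with `profiles` (regions x depths matrix), `y` (midsurface
#'   y-coordinate per region), `blocks` (block label per region), `seed`.
#' @export
simulate_intensity_profiles <- function(n_regions = 60, n_surfaces = 16,
                                        n_blocks = 4, noise_sd = 0.3,
                                        y_trend = 0.02, seed = 1L) {
  if (n_surfaces < 2) stop_param("n_surfaces must be >= 2")
  set.seed(seed)
  templates <- matrix(0, n_blocks, n_surfaces)
  for (b in seq_len(n_blocks)) {
    raw <- cumsum(rnorm(n_surfaces))
    sm <- stats::filter(raw, rep(1 / 3, 3), sides = 2)
    sm[is.na(sm)] <- raw[is.na(sm)]
    templates[b, ] <- as.numeric(scale(as.numeric(sm)))
  }
  blocks <- sort(rep_len(seq_len(n_blocks), n_regions))
  y <- runif(n_regions, 0, 170)
  depth_coef <- runif(n_surfaces, 0.5, 1.5)      # y trend varies with depth
  prof <- templates[blocks, , drop = FALSE] +
    matrix(rnorm(n_regions * n_surfaces, 0, noise_sd), n_regions) +
    outer(y * y_trend, depth_coef)
  rownames(prof) <- paste0("R", seq_len(n_regions) - 1L)
  colnames(prof) <- paste0("v", seq_len(n_surfaces))
  list(profiles = prof, y = y, blocks = paste0("B", blocks), seed = seed)
}
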