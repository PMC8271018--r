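# Edge-wise biometric variance decomposition (ACTE family) for twin-plus-
# sibling cohorts: IQR outlier filtering, maximum-likelihood fitting of
# family-block multivariate normal models with age/sex covariates in the
# mean, AIC model selection, and cohort-level summaries.
#
# Family covariance structure (per member variance a2 + c2 + t2 + e2):
#   cov(MZ twins)      = a2 + c2 + t2
#   cov(DZ twins)      = 0.5 a2 + c2 + t2
#   cov(twin, sibling) = 0.5 a2 + c2        (either zygosity)

BIOMETRIC_MODELS <- c("ACTE", "ACE", "AE", "CE", "E")

model_free_paths <- function(model) {
  switch(model,
         ACTE = c("a", "c", "t", "e"),
         ACE = c("a", "c", "e"),
         AE = c("a", "e"),
         CE = c("c", "e"),
         E = "e",
         stop_param("unknown biometric model '%s'", model))
}

#' Tukey-fence outlier filter with interpolated quartiles
#'
#' Retains values `w` with `Q1 - 1.5 IQR < w < Q3 + 1.5 IQR` (strict
#' inequalities), where the quartiles are computed by linear interpolation
#' of the order statistics (the default `quantile` type 7 convention, which
#' is used consistently throughout the package). A constant vector is left
#' untouched.
#'
#' @param values numeric vector (NA allowed; at least 4 finite values).
#' @return list with `values` (retained), `keep` (logical mask aligned with
#'   the input; NA inputs are FALSE), `bounds` (lower, upper).
#' @export
iqr_filter <- function(values) {
  finite <- is.finite(values)
  if (sum(finite) < 4) stop_param("need at least 4 finite values")
  q <- quantile(values[finite], c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[2] + 1.5 * iqr
  keep <- finite & values > lo & values < hi
  if (iqr == 0) keep <- finite    # all identical: nothing removed
  list(values = values[keep], keep = keep, bounds = c(lower = lo, upper = hi))
}

# Sharing matrices for a family's observed members, from their roles.
family_share_matrices <- function(roles, zygosity) {
  m <- length(roles)
  twin <- roles != "sibling"
  RA <- matrix(0.5, m, m)
  if (zygosity == "MZ") RA[twin, twin] <- 1
  diag(RA) <- 1
  RC <- matrix(1, m, m)
  RT <- matrix(0, m, m)
  RT[twin, twin] <- 1
  diag(RT) <- 1
  list(RA = RA, RC = RC, RT = RT)
}

# Group a cohort's observed phenotype values by family pattern. A pattern is
# (zygosity, observed roles); each group stores the response matrix Y
# (families x members), the per-member design matrices X_i (families x q),
# and precomputed cross-products used by the concentrated likelihood.
build_family_layout <- function(subjects, y, covariates = c("age", "sex")) {
  obs <- is.finite(y)
  X_all <- cbind(`(Intercept)` = 1,
                 as.matrix(subjects[, covariates, drop = FALSE]))
  q <- ncol(X_all)
  fam_ids <- unique(subjects$family_id[obs])
  keys <- character(0)
  groups <- list()
  for (f in fam_ids) {
    rows <- which(subjects$family_id == f & obs)
    if (length(rows) < 1) next
    roles <- subjects$role[rows]
    ord <- order(match(roles, c("twin1", "twin2", "sibling")))
    rows <- rows[ord]; roles <- roles[ord]
    zyg <- subjects$zygosity[rows[1]]
    key <- paste(zyg, paste(roles, collapse = "+"))
    if (!key %in% keys) {
      keys <- c(keys, key)
      groups[[key]] <- list(zygosity = zyg, roles = roles, rows = list())
    }
    groups[[key]]$rows[[length(groups[[key]]$rows) + 1L]] <- rows
  }
  layout <- lapply(groups, function(g) {
    rows <- do.call(rbind, g$rows)        # families x members
    m <- length(g$roles)
    share <- family_share_matrices(g$roles, g$zygosity)
    Y <- matrix(y[rows], ncol = m)
    Xl <- lapply(seq_len(m), function(i) X_all[rows[, i], , drop = FALSE])
    # cross-products t(X_i) X_j and t(X_i) y_j, reused at every likelihood
    # evaluation of the concentrated (GLS-profiled) objective
    XtX <- array(0, c(q, q, m, m))
    Xty <- array(0, c(q, m, m))
    for (i in seq_len(m)) for (j in seq_len(m)) {
      XtX[, , i, j] <- crossprod(Xl[[i]], Xl[[j]])
      Xty[, i, j] <- crossprod(Xl[[i]], Y[, j])
    }
    list(m = m, n_fam = nrow(Y), Y = Y, X = Xl, XtX = XtX, Xty = Xty,
         share = share)
  })
  tot_members <- sum(vapply(layout, function(g) g$m * g$n_fam, numeric(1)))
  list(groups = layout, q = q, n_obs = tot_members,
       n_informative_families = sum(vapply(
         layout, function(g) if (g$m >= 2) g$n_fam else 0L, numeric(1))))
}

# Concentrated negative log-likelihood for path coefficients `paths`
# (named subset of a,c,t,e; variances are their squares). Returns the
# -loglik, with betahat and components as attributes when `details = TRUE`.
biometric_negloglik <- function(paths, layout, details = FALSE) {
  v <- setNames(numeric(4), c("a", "c", "t", "e"))
  v[names(paths)] <- paths^2
  q <- layout$q
  A <- matrix(0, q, q)
  b <- numeric(q)
  pre <- lapply(layout$groups, function(g) {
    sigma <- v["a"] * g$share$RA + v["c"] * g$share$RC +
      v["t"] * g$share$RT + v["e"] * diag(g$m)
    V <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(V)) return(NULL)
    list(inv = chol2inv(V), logdet = 2 * sum(log(diag(V))))
  })
  if (any(vapply(pre, is.null, logical(1)))) return(list(value = 1e10))
  for (gi in seq_along(layout$groups)) {
    g <- layout$groups[[gi]]
    inv <- pre[[gi]]$inv
    for (i in seq_len(g$m)) for (j in seq_len(g$m)) {
      if (inv[i, j] == 0) next
      A <- A + inv[i, j] * g$XtX[, , i, j]
      b <- b + inv[i, j] * g$Xty[, i, j]
    }
  }
  beta <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(beta)) return(list(value = 1e10))
  nll <- 0
  for (gi in seq_along(layout$groups)) {
    g <- layout$groups[[gi]]
    inv <- pre[[gi]]$inv
    R <- g$Y
    for (i in seq_len(g$m)) R[, i] <- R[, i] - g$X[[i]] %*% beta
    quad <- 0
    for (i in seq_len(g$m)) for (j in seq_len(g$m)) {
      if (inv[i, j] == 0) next
      quad <- quad + inv[i, j] * sum(R[, i] * R[, j])
    }
    nll <- nll + 0.5 * (g$n_fam * (pre[[gi]]$logdet +
                                     g$m * log(2 * pi)) + quad)
  }
  out <- list(value = nll)
  if (details) {
    out$beta <- beta
    out$variances <- v
  }
  out
}

# Moment-based starting values on the path-coefficient scale.
biometric_start <- function(layout, free) {
  vals <- unlist(lapply(layout$groups, function(g) as.numeric(g$Y)))
  v_tot <- max(var(vals), 1e-6)
  covs <- list(MZ = numeric(0), DZ = numeric(0))
  for (g in layout$groups) {
    twin_cols <- which(g$roles != "sibling")
    if (length(twin_cols) == 2 && g$n_fam > 2) {
      cv <- stats::cov(g$Y[, twin_cols[1]], g$Y[, twin_cols[2]])
      key <- if (isTRUE(all.equal(g$share$RA[twin_cols[1], twin_cols[2]], 1)))
        "MZ" else "DZ"
      covs[[key]] <- c(covs[[key]], cv)
    }
  }
  cmz <- if (length(covs$MZ)) mean(covs$MZ) else 0.3 * v_tot
  cdz <- if (length(covs$DZ)) mean(covs$DZ) else 0.15 * v_tot
  a2 <- min(max(2 * (cmz - cdz), 0.05 * v_tot), 0.9 * v_tot)
  c2 <- min(max(2 * cdz - cmz, 0.02 * v_tot), 0.5 * v_tot)
  t2 <- 0.05 * v_tot
  e2 <- max(v_tot - a2 - c2 - t2, 0.05 * v_tot)
  full <- c(a = sqrt(a2), c = sqrt(c2), t = sqrt(t2), e = sqrt(e2))
  start <- full[free]
  if (!"a" %in% free || !"c" %in% free) {
    # reallocate dropped variance into e so total variance is preserved
    dropped <- sum(full[setdiff(c("a", "c", "t"), free)]^2)
    start["e"] <- sqrt(full["e"]^2 + dropped)
  }
  start
}

#' Fit one biometric variance-component model to an edge phenotype
#'
#' Maximizes the product over families of multivariate-normal likelihoods
#' with mean `mu + beta_age * age + beta_sex * sex` and a covariance built
#' from the classical sharing coefficients (see the module header). Families
#' with missing members contribute the marginal likelihood of their observed
#' members. Nonnegativity of variance components is enforced by optimizing
#' path coefficients (variances are squares). The mean/covariate
#' coefficients are concentrated out by generalized least squares at every
#' objective evaluation, which is exactly equivalent to joint maximum
#' likelihood. Multi-start quasi-Newton optimization is used: one
#' moment-based start plus random restarts, stopping early once two starts
#' agree to 1e-6 in log-likelihood.
#'
#' @param y numeric phenotype vector over subjects (NA = missing).
#' @param subjects subject table: family_id, zygosity (`"MZ"`/`"DZ"`), role
#'   (`"twin1"`, `"twin2"`, `"sibling"`), plus covariate columns.
#' @param model one of `"ACTE"`, `"ACE"`, `"AE"`, `"CE"`, `"E"`.
#' @param covariates covariate column names entering the mean model.
#' @param n_starts maximum number of optimizer starts (default 5).
#' @param layout optional precomputed [build_family_layout()] result.
#' @param seed optional seed for the random restarts.
#' @return list of class `biometric_fit`: model, variance components raw
#'   (`vc`) and standardized (`std`, summing to 1), `h2`, covariate
#'   coefficients `beta`, `loglik`, `npar`, `aic`, `converged`, `n_obs`.
#' @export
fit_biometric_model <- function(y, subjects, model = "ACTE",
                                covariates = c("age", "sex"), n_starts = 5,
                                layout = NULL, seed = NULL) {
  model <- match.arg(model, BIOMETRIC_MODELS)
  if (is.null(layout)) layout <- build_family_layout(subjects, y, covariates)
  if (layout$n_informative_families < 2)
    stop_param("need at least 2 families with at least 2 phenotyped members")
  free <- model_free_paths(model)
  obj <- function(par) biometric_negloglik(setNames(par, free), layout)$value

  if (!is.null(seed)) set.seed(seed)
  start0 <- biometric_start(layout, free)
  scale0 <- sqrt(max(c(unlist(lapply(layout$groups,
                                     function(g) var(as.numeric(g$Y)))),
                       1e-6), na.rm = TRUE))
  best <- NULL
  n_good <- 0L
  for (s in seq_len(n_starts)) {
    par0 <- if (s == 1) start0 else abs(rnorm(length(free), 0, scale0)) + 1e-3
    fit <- tryCatch(
      optim(par0, obj, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e9) next
    if (is.null(best) || fit$value < best$value - 1e-6) {
      best <- fit
      n_good <- 1L
    } else if (abs(fit$value - best$value) <= 1e-6) {
      n_good <- n_good + 1L
      if (fit$value < best$value) best <- fit
    }
    if (n_good >= 2) break
  }
  if (is.null(best)) {
    return(structure(list(model = model,
                          vc = setNames(rep(NaN, 4), c("a2","c2","t2","e2")),
                          std = setNames(rep(NaN, 4), c("a2","c2","t2","e2")),
                          h2 = NaN, beta = NULL, loglik = NaN,
                          npar = length(free) + layout$q, aic = Inf,
                          converged = FALSE, n_obs = layout$n_obs),
                     class = "biometric_fit"))
  }
  det <- biometric_negloglik(setNames(best$par, free), layout,
                             details = TRUE)
  v <- det$variances
  vc <- setNames(as.numeric(v), c("a2", "c2", "t2", "e2"))
  std <- vc / sum(vc)
  npar <- length(free) + layout$q
  loglik <- -best$value
  structure(list(model = model, vc = vc, std = std, h2 = unname(std["a2"]),
                 beta = det$beta, loglik = loglik, npar = npar,
                 aic = 2 * npar - 2 * loglik,
                 converged = TRUE, n_obs = layout$n_obs),
            class = "biometric_fit")
}

#' @export
print.biometric_fit <- function(x, ...) {
  cat(sprintf("<biometric_fit %s> h2 = %.3f, logLik = %.2f, AIC = %.2f\n",
              x$model, x$h2, x$loglik, x$aic))
  cat("  standardized components:",
      paste(sprintf("%s=%.3f", names(x$std), x$std), collapse = ", "), "\n")
  invisible(x)
}

#' Select the best biometric model by AIC
#'
#' Picks the converged candidate with the lowest AIC; exact ties are broken
#' toward the model with fewer parameters.
#'
#' @param fits list of `biometric_fit` objects (e.g. one per candidate
#'   model).
#' @return The selected fit, with the selected model label in `$model`.
#'   Errors if no candidate converged.
#' @export
select_model <- function(fits) {
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (!any(ok)) stop_param("no converged fit to select from")
  fits <- fits[ok]
  aics <- vapply(fits, `[[`, numeric(1), "aic")
  npars <- vapply(fits, `[[`, numeric(1), "npar")
  best_aic <- min(aics)
  cand <- which(aics <= best_aic + 1e-9)
  fits[[cand[which.min(npars[cand])]]]
}

#' Edge-wise heritability screen
#'
#' For every edge: applies the IQR outlier filter to the phenotype, fits all
#' candidate biometric models, selects by AIC, and reports the standardized
#' components of the best model together with the heritability taken from
#' the full ACTE model (when ACTE is among the candidates), so that
#' model-selection artifacts can be checked.
#'
#' @param cohort a `family_cohort` (see [simulate_twin_cohort()]) or a list
#'   with `subjects` and `phenotypes`.
#' @param edges edge columns to analyse: indices or column names of the
#'   phenotype matrix (default: all).
#' @param models candidate models (default all five).
#' @param covariates covariate columns in `subjects`.
#' @param n_starts optimizer starts per fit.
#' @param outlier_filter apply [iqr_filter()] per edge (default TRUE).
#' @param seed optional integer seed (restart randomness).
#' @return list of class `heritability_screen`: `edges` (data.frame: edge,
#'   best_model, a2, c2, t2, e2, h2, h2_acte, loglik, aic, n_used,
#'   n_outliers) and `proportions` (share of edges per best model, summing
#'   to 1 over fitted edges).
#' @export
edgewise_heritability <- function(cohort, edges = NULL,
                                  models = BIOMETRIC_MODELS,
                                  covariates = c("age", "sex"),
                                  n_starts = 5, outlier_filter = TRUE,
                                  seed = NULL) {
  subjects <- cohort$subjects
  pheno <- cohort$phenotypes
  if (is.null(edges)) edges <- seq_len(ncol(pheno))
  if (is.character(edges)) {
    if (!all(edges %in% colnames(pheno)))
      stop_param("edge labels absent from the phenotype matrix")
    edges <- match(edges, colnames(pheno))
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", length(edges))
  for (idx in seq_along(edges)) {
    e <- edges[idx]
    y <- pheno[, e]
    n_out <- 0L
    if (outlier_filter && sum(is.finite(y)) >= 4) {
      filt <- iqr_filter(y)
      n_out <- sum(is.finite(y)) - sum(filt$keep)
      y[!filt$keep] <- NA_real_
    }
    label <- colnames(pheno)[e] %||% as.character(e)
    layout <- tryCatch(build_family_layout(subjects, y, covariates),
                       error = function(err) NULL)
    fits <- list()
    if (!is.null(layout) && layout$n_informative_families >= 2) {
      fits <- lapply(models, function(m)
        fit_biometric_model(y, subjects, m, covariates,
                            n_starts = n_starts, layout = layout))
    }
    ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    if (!length(fits) || !any(ok)) {
      rows[[idx]] <- data.frame(edge = label, best_model = NA_character_,
                                a2 = NaN, c2 = NaN, t2 = NaN, e2 = NaN,
                                h2 = NaN, h2_acte = NaN, loglik = NaN,
                                aic = NaN, n_used = sum(is.finite(y)),
                                n_outliers = n_out,
                                stringsAsFactors = FALSE)
      next
    }
    best <- select_model(fits)
    acte <- fits[[match("ACTE", models)]]
    h2_acte <- if (!is.na(match("ACTE", models)) &&
                   isTRUE(acte$converged)) acte$h2 else NA_real_
    rows[[idx]] <- data.frame(edge = label, best_model = best$model,
                              a2 = best$std["a2"], c2 = best$std["c2"],
                              t2 = best$std["t2"], e2 = best$std["e2"],
                              h2 = best$h2, h2_acte = h2_acte,
                              loglik = best$loglik, aic = best$aic,
                              n_used = best$n_obs, n_outliers = n_out,
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  fitted <- tab$best_model[!is.na(tab$best_model)]
  props <- if (length(fitted)) table(factor(fitted, levels = models)) /
    length(fitted) else table(factor(character(0), levels = models))
  structure(list(edges = tab, proportions = c(props)),
            class = "heritability_screen")
}

#' @export
print.heritability_screen <- function(x, ...) {
  cat(sprintf("<heritability_screen> %d edges; mean h2 = %.3f\n",
              nrow(x$edges), mean(x$edges$h2, na.rm = TRUE)))
  cat("  best-model proportions:",
      paste(sprintf("%s=%.1f%%", names(x$proportions),
                    100 * x$proportions), collapse = ", "), "\n")
  invisible(x)
}
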