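# End-to-end orchestration: runs the synthetic-data generators and analysis
# stages in dependency order, writes tidy TSV outputs into a run directory,
# and records a provenance manifest (parameters, seeds, file digests).

#' Default pipeline configuration
#'
#' Returns the configuration list consumed by [run_pipeline()], sized for a
#' quick synthetic end-to-end run. Every field can be overridden.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @return Named list of stage settings.
#' @export
default_pipeline_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    stages = c("simulate", "connectome", "richclub", "comm", "herit",
               "cge", "gcs", "enrich", "mpc", "grow", "optimize", "report"),
    n_nodes = 40, n_subjects = 20,
    consistency_min = 0.30, density_target = 0.20,
    n_null = 50,
    herit_edges = 12,
    n_mz_pairs = 117, n_dz_pairs = 60, n_mz_sibs = 69, n_dz_sibs = 48,
    n_genes = 120, gsr_iter = 500, n_sets = 30,
    n_profiles_blocks = 4,
    grow_rule = "deg-avg", grow_eta = -2, grow_gamma = 1,
    optimize_rule = "sptl", optimize_per_round = 10, optimize_rounds = 2
  )
}

pipeline_log <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the synthetic end-to-end analysis pipeline
#'
#' Executes the requested stages in dependency order
#' (simulate -> connectome -> richclub/comm -> herit -> cge/gcs/enrich ->
#' mpc -> grow/optimize -> report), writing per-stage TSV outputs and a
#' provenance manifest (`manifest.json` with versions, seeds, parameters
#' and md5 digests of every written file) into `out_dir`. Reruns with the
#' same configuration produce byte-identical outputs.
#'
#' @param config configuration list (see [default_pipeline_config()]);
#'   partial lists are merged over the defaults.
#' @param out_dir run directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = list(), out_dir) {
  cfg <- default_pipeline_config()
  cfg[names(config)] <- config
  if (missing(out_dir) || !nzchar(out_dir))
    stop_param("configuration error: out_dir is required")
  for (f in c("input_paths")) {
    if (!is.null(cfg[[f]]) && !all(file.exists(unlist(cfg[[f]]))))
      stop_param("configuration error: missing input path(s): %s",
                 paste(unlist(cfg[[f]])[!file.exists(unlist(cfg[[f]]))],
                       collapse = ", "))
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_con <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(log_con), add = TRUE)
  written <- character(0)
  emit <- function(x, name) {
    path <- file.path(out_dir, name)
    if (is.matrix(x)) write_matrix_csv(x, path) else write_tsv_table(x, path)
    written <<- c(written, path)
    path
  }
  stage_on <- function(s) s %in% cfg$stages
  seed_of <- function(k) child_seed(cfg$seed, k)

  cohort <- conn <- fa_weights <- expr <- decay <- cge_res <- NULL
  sim <- NULL

  if (stage_on("simulate")) {
    pipeline_log(log_con, "simulate: %d nodes, %d subjects",
                 cfg$n_nodes, cfg$n_subjects)
    sim <- simulate_cohort_connectomes(cohort_spec(
      n_nodes = cfg$n_nodes, n_subjects = cfg$n_subjects,
      seed = seed_of(1)))
    emit(sim$nodes, "nodes.tsv")
  }
  if (stage_on("connectome")) {
    if (is.null(sim)) stop_param("stage 'connectome' requires 'simulate'")
    conn <- build_group_connectome(
      lapply(sim$subjects, `[[`, "sc"),
      consistency_min = cfg$consistency_min,
      density_target = cfg$density_target, nodes = sim$nodes)
    fa_weights <- group_edge_statistic(lapply(sim$subjects, `[[`, "fa"),
                                       mask = conn$mask)
    pipeline_log(log_con, "connectome: %d edges retained (density %.3f)",
                 sum(conn$mask) / 2, conn$density)
    write_edge_list(conn, file.path(out_dir, "group_connectome.tsv"))
    written <- c(written, file.path(out_dir, "group_connectome.tsv"))
  }
  if (stage_on("richclub")) {
    rc <- normalized_rich_club_curve(conn, n_null = cfg$n_null,
                                     mode = "binary", seed = seed_of(2))
    emit(as.data.frame(rc), "rich_club_binary.tsv")
    rcw <- normalized_rich_club_curve(conn, n_null = cfg$n_null,
                                      mode = "weighted", seed = seed_of(3))
    emit(as.data.frame(rcw), "rich_club_weighted.tsv")
    pipeline_log(log_con, "richclub: max Phi_norm = %.3f",
                 max(rc$phi_norm, na.rm = TRUE))
  }
  if (stage_on("comm")) {
    cm <- communicability(conn, "weighted")
    ed <- connectome_edges(conn)
    curve <- link_type_curve(conn, cm[cbind(ed$i, ed$j)])
    emit(as.data.frame(curve), "communicability_curve.tsv")
  }
  if (stage_on("herit")) {
    ed <- connectome_edges(conn)
    n_e <- min(cfg$herit_edges, nrow(ed))
    tw <- simulate_twin_cohort(twin_spec(
      n_mz_pairs = cfg$n_mz_pairs, n_dz_pairs = cfg$n_dz_pairs,
      n_mz_sibs = cfg$n_mz_sibs, n_dz_sibs = cfg$n_dz_sibs,
      seed = seed_of(4)), n_edges = n_e)
    scr <- edgewise_heritability(tw, seed = seed_of(5))
    pipeline_log(log_con, "herit: mean h2 = %.3f over %d edges",
                 mean(scr$edges$h2, na.rm = TRUE), n_e)
    emit(scr$edges, "heritability.tsv")
    emit(data.frame(model = names(scr$proportions),
                    proportion = as.numeric(scr$proportions)),
         "model_proportions.tsv")
  }
  if (stage_on("cge")) {
    expr_sim <- simulate_expression(expression_spec(
      n_genes = cfg$n_genes, seed = seed_of(6)), sim$nodes, sim$hubs)
    expr <- srs_normalize(expr_sim$expr)
    cge <- cge_matrix(expr)
    decay <- fit_distance_decay(cge, expr_sim$distances)
    cge_res <- decay$residuals
    pipeline_log(log_con, "cge: decay A=%.3f B=%.3f n=%.1f",
                 decay$A, decay$B, decay$n)
    emit(data.frame(A = decay$A, B = decay$B, n = decay$n), "decay_fit.tsv")
    ed <- connectome_edges(conn)
    curve <- link_type_curve(conn, cge_res[cbind(ed$i, ed$j)])
    emit(as.data.frame(curve), "cge_curve.tsv")
  }
  if (stage_on("gcs")) {
    ed <- connectome_edges(conn)
    gcs <- gene_contribution_scores(expr, decay, ed,
                                    coord_dist(as.matrix(
                                      sim$nodes[, c("x", "y", "z")])))
    cl <- classify_links(conn, quantile(node_degrees(conn), 0.75))
    ts <- gcs_link_tstat(gcs, which(cl$edges$class == "rich"),
                         which(cl$edges$class == "peripheral"))
    emit(ts, "gcs_tstat.tsv")
  }
  if (stage_on("enrich")) {
    ts <- read_tsv_table(file.path(out_dir, "gcs_tstat.tsv"))
    scores <- setNames(ts$t, ts$gene)
    scores <- scores[is.finite(scores)]
    set.seed(seed_of(7))
    sets <- lapply(seq_len(cfg$n_sets), function(i)
      sample(names(scores), sample(5:20, 1)))
    names(sets) <- paste0("SET", seq_along(sets))
    gsr <- gene_score_resampling(scores, sets, n_iter = cfg$gsr_iter,
                                 seed = seed_of(8))
    emit(as.data.frame(gsr), "gsr.tsv")
    pipeline_log(log_con, "enrich: %d sets, min q = %.3f",
                 nrow(gsr), min(gsr$q))
  }
  if (stage_on("mpc")) {
    prof <- simulate_intensity_profiles(n_regions = cfg$n_nodes,
                                        n_blocks = cfg$n_profiles_blocks,
                                        seed = seed_of(9))
    res <- residualize_profiles(prof$profiles, prof$y)
    mp <- mpc_matrix(res)
    ed <- connectome_edges(conn)
    curve <- link_type_curve(conn, mpc_edge_values(mp, ed))
    emit(as.data.frame(curve), "mpc_curve.tsv")
  }
  if (stage_on("grow")) {
    d <- sim$distances
    net <- grow_network(cfg$grow_rule, n_edges = sum(conn$mask) / 2,
                        distances = d, eta = cfg$grow_eta,
                        gamma = cfg$grow_gamma, seed = seed_of(10))
    er <- model_energy(net$adj, conn$mask, d)
    pipeline_log(log_con, "grow: %s energy = %.3f, degseq rho = %.3f",
                 cfg$grow_rule, er$energy, er$degseq_rho)
    emit(data.frame(net$order, order = seq_len(nrow(net$order))),
         "grown_edges.tsv")
    emit(data.frame(stat = names(er$ks), ks = as.numeric(er$ks),
                    energy = er$energy, degseq_rho = er$degseq_rho),
         "energy.tsv")
  }
  if (stage_on("optimize")) {
    tr <- optimize_parameters(cfg$optimize_rule, conn$mask, sim$distances,
                              n_per_round = cfg$optimize_per_round,
                              n_rounds = cfg$optimize_rounds,
                              seed = seed_of(11))
    emit(tr$evaluations, "optimization_trace.tsv")
    pipeline_log(log_con, "optimize: best energy = %.3f", tr$best$objective)
  }

  manifest <- list(
    package = "connherit",
    version = as.character(utils::packageVersion("connherit")),
    r_version = R.version.string,
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "stages")],
    stages = cfg$stages,
    outputs = lapply(stats::setNames(written, basename(written)),
                     function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  pipeline_log(log_con, "report: manifest written (%d outputs)",
               length(written))
  invisible(manifest)
}
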