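#!/usr/bin/env Rscript
# Stage 3: edge-wise biometric (ACTE-family) heritability screen.
#
# Twin phenotypes are simulated on the group connectome's edges with higher
# additive-genetic variance planted on rich (hub-hub) links (a2 = 0.8 vs
# 0.2), at the emulated cohort structure: 117 MZ pairs + 69 siblings and
# 60 DZ pairs + 48 siblings. Each edge gets the IQR outlier filter, all
# five candidate models, and AIC selection; the resulting per-edge h2 is
# compared across rich/feeder/peripheral links.

library(connherit)
out <- "results"
SEED <- 2026L

sim <- simulate_cohort_connectomes(
  cohort_spec(n_nodes = 50, n_subjects = 25, hub_fraction = 0.14,
              richclub_boost = 0.8, hub_degree_boost = 0.2,
              decay_scale = 400, base_prob = 0.25, seed = SEED))
conn <- build_group_connectome(lapply(sim$subjects, `[[`, "sc"),
                               0.30, 0.15, nodes = sim$nodes)
ed <- connectome_edges(conn)
hub <- seq_len(nrow(conn$mask)) %in% sim$hubs
rich <- hub[ed$i] & hub[ed$j]
a2 <- ifelse(rich, 0.8, 0.2)

tw <- simulate_twin_cohort(twin_spec(a2 = a2, c2 = 0, t2 = 0, e2 = 1 - a2,
                                     seed = SEED + 1), n_edges = nrow(ed))
scr <- edgewise_heritability(tw, seed = SEED + 2)
print(scr)
write_tsv_table(scr$edges, file.path(out, "heritability.tsv"))
write_tsv_table(data.frame(model = names(scr$proportions),
                           proportion = as.numeric(scr$proportions)),
                file.path(out, "model_proportions.tsv"))

deg <- node_degrees(conn)
k_planted <- seq(max(deg[!hub]), min(deg[hub]) - 1)
curve <- link_type_curve(conn, scr$edges$h2)
write_tsv_table(as.data.frame(curve), file.path(out, "h2_link_curve.tsv"))
rich_rows <- subset(curve, class == "rich" & k %in% k_planted)
cat(sprintf("rich-link h2 = %.2f vs network mean %.2f; Welch p <= %.2g at the planted thresholds\n",
            mean(rich_rows$mean), attr(curve, "global_mean"),
            max(rich_rows$p)))
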