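#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# A geometric cohort of weighted connectomes with planted, spatially
# distributed hubs; a twin-plus-sibling cohort with known variance
# fractions; a region x gene expression atlas whose coupling decays
# exponentially with distance and is boosted between hubs; and depth-wise
# intensity profiles with block cytoarchitecture. Later stages regenerate
# the same objects deterministically from the seeds recorded here; this
# stage writes the human-readable input tables.

library(connherit)
out <- "results"
dir.create(out, showWarnings = FALSE)

SEED <- 2026L

spc <- cohort_spec(n_nodes = 100, n_subjects = 40, hub_fraction = 0.12,
                   richclub_boost = 0.6, seed = SEED)
sim <- simulate_cohort_connectomes(spc)
write_tsv_table(sim$nodes, file.path(out, "nodes.tsv"))
cat(sprintf("simulated %d subjects x %d nodes; %d planted hubs\n",
            spc$n_subjects, spc$n_nodes, length(sim$hubs)))

tw <- simulate_twin_cohort(twin_spec(seed = SEED), n_edges = 50)
write_tsv_table(tw$subjects, file.path(out, "family_table.tsv"))
cat(sprintf("twin cohort: %d subjects in %d families\n",
            nrow(tw$subjects), length(unique(tw$subjects$family_id))))

ex <- simulate_expression(expression_spec(n_genes = 400, seed = SEED),
                          sim$nodes, sim$hubs)
write_tsv_table(data.frame(region = rownames(ex$expr),
                           round(as.data.frame(ex$expr), 5)),
                file.path(out, "expression.tsv"))
write_tsv_table(ex$gene_classes, file.path(out, "gene_classes.tsv"))

pr <- simulate_intensity_profiles(n_regions = 100, n_blocks = 5, seed = SEED)
write_tsv_table(data.frame(region = rownames(pr$profiles), y = pr$y,
                           block = pr$blocks,
                           round(as.data.frame(pr$profiles), 5)),
                file.path(out, "intensity_profiles.tsv"))
cat("input tables written to results/\n")
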