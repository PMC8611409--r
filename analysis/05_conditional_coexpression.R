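#!/usr/bin/env Rscript
# Stage 5: conditional co-expression of TCA-cycle edges.
#
# Simulates five expression compendia (development, root, pollen,
# osmotic, salt) over the TCA subnetwork's genes, planting strong
# (r = 0.9) TF-target correlations that are exclusive to single
# datasets — mostly the osmotic/salt pair, mirroring the stress-skewed
# conditionality such screens report. Each edge's Pearson r is computed
# per dataset and edges are partitioned by the set of datasets in which
# |r| >= 0.8.

library(y1hnet)
seed <- 1L
in_dir <- "results/screen"

net <- read_edge_list(file.path(in_dir, "edges.tsv"),
                      pathway_file = file.path(in_dir, "pathways.tsv"))
sub <- extract_subnetwork(net, "TCA_cycle")

# plant one exclusive correlation per distinct target, skewed toward
# the stress datasets
e <- sub$edges[!duplicated(sub$edges$promoter_id), ]
set.seed(seed)
pl <- data.frame(tf_id = e$tf_id, target_id = e$promoter_id,
                 dataset = sample(c("development", "root", "pollen",
                                    "osmotic", "salt"),
                                  nrow(e), replace = TRUE,
                                  prob = c(0.15, 0.1, 0.05, 0.35, 0.35)),
                 r = 0.9)
cs <- coexpr_sim_spec(planted_edges = pl, seed = seed)
datasets <- simulate_coexpression(cs, sub)

profiles <- edge_correlations(sub, datasets)
part <- classify_conditionality(profiles, threshold = 0.8)
print(part)

utils::write.table(merge(profiles, part$per_edge),
                   "results/edge_correlations.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
venn <- data.frame(dataset_set = names(part$venn_counts),
                   n_edges = as.integer(part$venn_counts))
utils::write.table(venn[order(-venn$n_edges), ],
                   "results/coexpression_venn.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("%d of %d edges co-expressed in >= 1 dataset; %d (%.0f%%) exclusive to one",
                part$n_pass_any, nrow(profiles), part$n_exclusive,
                100 * part$n_exclusive / max(1, part$n_pass_any)))
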