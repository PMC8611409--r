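#!/usr/bin/env Rscript
# Stage 2: network topology.
#
# Loads the screen's edge list, summarises the bipartite topology
# (degree distribution, pathway multiplicity of TFs), extracts the
# TCA-cycle subnetwork, and exports Cytoscape-ready files.

library(y1hnet)
in_dir <- "results/screen"

net <- read_edge_list(file.path(in_dir, "edges.tsv"),
                      pathway_file = file.path(in_dir, "pathways.tsv"),
                      family_file = file.path(in_dir, "families.tsv"),
                      localization_file = file.path(in_dir, "localization.tsv"))
s <- network_summary(net)
print(s)

frac2 <- pathway_multiplicity_fraction(net, 2L)
message(sprintf("%.1f%% of detected TFs bind promoters in two or more pathways",
                100 * frac2))

mult <- s$tf_pathway_multiplicity
utils::write.table(
  data.frame(n_pathways = names(mult), n_tfs = as.integer(mult)),
  "results/tf_pathway_multiplicity.tsv",
  sep = "\t", quote = FALSE, row.names = FALSE)

sub <- extract_subnetwork(net, "TCA_cycle")
ssub <- network_summary(sub)
message(sprintf("TCA-cycle subnetwork: %d interactions between %d TFs and %d genes",
                ssub$n_edges, ssub$n_tfs, ssub$n_promoters))

write_sif(net, "results/network.sif")
write_graphml(sub, "results/tca_subnetwork.graphml")

utils::write.table(
  data.frame(statistic = c("n_edges", "n_tfs", "n_promoters",
                           "n_promoters_hitfree", "degree_min", "degree_max",
                           "degree_mean", "frac_tfs_ge2_pathways",
                           "tca_edges", "tca_tfs", "tca_genes"),
             value = c(s$n_edges, s$n_tfs, s$n_promoters,
                       s$n_promoters_hitfree, s$promoter_degree_min,
                       s$promoter_degree_max, round(s$promoter_degree_mean, 2),
                       round(frac2, 4), ssub$n_edges, ssub$n_tfs,
                       ssub$n_promoters)),
  "results/network_summary.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/network_summary.tsv")
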