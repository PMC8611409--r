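# localization resolution and TF-family x enzyme-step x compartment enrichment

test_that("experimental localization evidence overrides the consensus", {
  tab <- data.frame(
    promoter_id = c("G1", "G1", "G2", "G3", "G3"),
    enzyme_step = c("FUM", "FUM", "MDH", "CSY", "CSY"),
    compartment = c("plastid", "mitochondrion", "cytosol", "plastid", "plastid"),
    evidence = c("consensus_predicted", "experimental",
                 "consensus_predicted", "consensus_predicted",
                 "consensus_predicted"),
    stringsAsFactors = FALSE)
  res <- resolve_localization(tab)
  expect_equal(res$compartment[res$promoter_id == "G1"], "mitochondrion")
  expect_equal(res$evidence[res$promoter_id == "G1"], "experimental")
  expect_equal(res$compartment[res$promoter_id == "G2"], "cytosol")
  expect_equal(nrow(res), 3)  # one row per gene

  conflict <- data.frame(
    promoter_id = c("G9", "G9"),
    enzyme_step = c("FUM", "FUM"),
    compartment = c("plastid", "mitochondrion"),
    evidence = c("experimental", "experimental"),
    stringsAsFactors = FALSE)
  expect_error(resolve_localization(conflict), "G9")
  expect_error(resolve_localization(data.frame(promoter_id = "G1",
                                               enzyme_step = "FUM",
                                               compartment = "plastid",
                                               evidence = "guessed")),
               "evidence")
})

test_that("family enrichment matches the enumeration oracle on a toy collection", {
  # 100-TF collection: 10 in family F, 90 others; 8 of F and 5 others
  # bind the single mitochondrial FUM gene
  collection <- data.frame(
    tf_id = sprintf("T%03d", 1:100),
    family = c(rep("F", 10), rep("other", 90)),
    stringsAsFactors = FALSE)
  binders <- c(sprintf("T%03d", 1:8), sprintf("T%03d", 11:15))
  net <- suppressMessages(regulatory_network(
    data.frame(tf_id = binders, promoter_id = "G1"),
    promoter_pathways = data.frame(promoter_id = "G1", pathway = "TCA"),
    tf_families = collection,
    localization = data.frame(promoter_id = "G1", enzyme_step = "FUM",
                              compartment = "mitochondrion",
                              evidence = "consensus_predicted")))
  res <- family_compartment_enrichment(net)
  row <- res[res$family == "F", ]
  expect_equal(unlist(row[c("a", "b", "c", "d")], use.names = FALSE),
               c(8, 2, 5, 85))
  expect_equal(row$p_raw, brute_two_sided(8, 2, 5, 85), tolerance = 1e-12)
  expect_equal(row$p_raw,
               fisher.test(matrix(c(8, 2, 5, 85), 2, byrow = TRUE))$p.value,
               tolerance = 1e-9)
  # margins: cells always sum to the collection size
  expect_true(all(res$a + res$b + res$c + res$d == 100))
  # percentage output: 8 of the 8+5=13 subnetwork TFs... family share
  expect_equal(row$pct_family_binding, 8 / 8)  # all F TFs in subnetwork bind
})

test_that("a family binding nothing gets a = 0 and is never significant", {
  collection <- data.frame(tf_id = sprintf("T%02d", 1:30),
                           family = rep(c("F", "G", "H"), each = 10),
                           stringsAsFactors = FALSE)
  net <- suppressMessages(regulatory_network(
    data.frame(tf_id = sprintf("T%02d", 11:16), promoter_id = "G1"),
    tf_families = collection,
    localization = data.frame(promoter_id = "G1", enzyme_step = "SDH",
                              compartment = "mitochondrion",
                              evidence = "consensus_predicted")))
  res <- family_compartment_enrichment(net)
  f_row <- res[res$family == "F", ]
  expect_equal(f_row$a, 0)
  expect_false(f_row$significant)
})

test_that("merging compartments never shrinks a family's binding count", {
  spec <- network_sim_spec(n_tfs = 300L, seed = 12, base_binding_prob = 0.05)
  net <- suppressMessages(simulate_network(spec))
  sub <- extract_subnetwork(net, "TCA_cycle")
  loc <- net$localization[net$localization$promoter_id %in%
                            unique(sub$edges$promoter_id), ]
  count_a <- function(fam, genes) {
    fam_tfs <- net$tf_families$tf_id[net$tf_families$family == fam]
    length(intersect(unique(sub$edges$tf_id[sub$edges$promoter_id %in% genes]),
                     fam_tfs))
  }
  steps <- unique(loc$enzyme_step)
  for (E in steps[1:min(3, length(steps))]) {
    g_mito <- loc$promoter_id[loc$enzyme_step == E &
                                loc$compartment == "mitochondrion"]
    g_plas <- loc$promoter_id[loc$enzyme_step == E &
                                loc$compartment == "plastid"]
    merged <- count_a("bHLH", c(g_mito, g_plas))
    expect_gte(merged, count_a("bHLH", g_mito))
    expect_gte(merged, count_a("bHLH", g_plas))
  }
})

test_that("Holm adjustment spans all annotated triples jointly", {
  spec <- network_sim_spec(n_tfs = 200L, seed = 8, base_binding_prob = 0.06)
  net <- suppressMessages(simulate_network(spec))
  sub <- extract_subnetwork(net, "TCA_cycle")
  res <- family_compartment_enrichment(sub, families = net$tf_families,
                                       localization = net$localization)
  expect_equal(res$p_adj, adjust_pvalues(res$p_raw, "Holm"))
  expect_true(all(res$p_adj >= res$p_raw - 1e-15))
})
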