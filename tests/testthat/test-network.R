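# bipartite network container, I/O, and topology statistics

test_that("edge lists are deduplicated and identifiers normalized", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("tf_id\tpromoter_id",
               "t1\tp1", "T1\tP1", "t1\tp2", "T2\tP1", "T2\tP2"), tsv)
  net <- suppressMessages(read_edge_list(tsv))
  expect_equal(nrow(net$edges), 4)  # one duplicate collapsed, case-insensitively
  expect_true(all(net$edges$tf_id %in% c("T1", "T2")))
})

test_that("missing columns, empty files, and bipartite violations behave as specified", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "x\ty"), tsv)
  expect_error(read_edge_list(tsv), "tf_id")

  writeLines("tf_id\tpromoter_id", tsv)   # header only: empty network, not an error
  net <- read_edge_list(tsv)
  expect_equal(network_summary(net)$n_edges, 0)

  expect_error(regulatory_network(
    data.frame(tf_id = c("T1", "P1"), promoter_id = c("P1", "P2"))),
    "bipartiteness")
})

test_that("summary counts match hand enumeration and conserve degree", {
  net <- toy_network()
  s <- network_summary(net)
  expect_equal(s$n_edges, 3)
  expect_equal(s$n_tfs, 2)
  expect_equal(s$n_promoters, 2)
  expect_equal(s$promoter_degree_mean, 1.5)
  # conservation: promoter degrees and TF degrees both sum to n_edges
  expect_equal(sum(table(net$edges$promoter_id)), s$n_edges)
  expect_equal(sum(table(net$edges$tf_id)), s$n_edges)
  # multiplicity counts partition the TFs
  expect_equal(sum(s$tf_pathway_multiplicity), s$n_tfs)
})

test_that("hit-free screened promoters are reported separately", {
  net <- suppressMessages(regulatory_network(
    data.frame(tf_id = "T1", promoter_id = "P1"),
    promoter_pathways = data.frame(promoter_id = c("P1", "P2", "P3"),
                                   pathway = c("A", "A", "B"))))
  s <- network_summary(net)
  expect_equal(s$n_promoters, 1)
  expect_equal(s$n_promoters_hitfree, 2)
})

test_that("pathway multiplicity fraction matches hand cases and is monotone in k", {
  net <- toy_network()
  expect_equal(pathway_multiplicity_fraction(net, 1), 1)
  expect_equal(pathway_multiplicity_fraction(net, 2), 0.5)  # only T1 spans A+B
  expect_equal(pathway_multiplicity_fraction(net, 3), 0)

  # single-pathway network: nothing can span two pathways
  one <- suppressMessages(regulatory_network(
    data.frame(tf_id = c("T1", "T2"), promoter_id = c("P1", "P2")),
    promoter_pathways = data.frame(promoter_id = c("P1", "P2"),
                                   pathway = c("A", "A"))))
  expect_equal(pathway_multiplicity_fraction(one, 2), 0)

  # monotone non-increasing in k_min on a simulated network
  spec <- network_sim_spec(n_tfs = 100L, seed = 5, base_binding_prob = 0.05)
  sim <- suppressMessages(simulate_network(spec))
  fr <- vapply(1:6, function(k) pathway_multiplicity_fraction(sim, k), 0)
  expect_true(all(diff(fr) <= 1e-12))

  # unannotated promoter is an error naming the offender
  bad <- suppressMessages(regulatory_network(
    data.frame(tf_id = "T1", promoter_id = c("P1", "PX")),
    promoter_pathways = data.frame(promoter_id = "P1", pathway = "A")))
  expect_error(pathway_multiplicity_fraction(bad, 2), "PX")
})

test_that("subnetwork extraction restricts edges and respects the annotation", {
  net <- toy_network()
  sub <- extract_subnetwork(net, "A")
  expect_equal(sort(paste(sub$edges$tf_id, sub$edges$promoter_id)),
               c("T1 P1", "T2 P1"))
  expect_error(extract_subnetwork(net, "nope"), "unknown pathway")

  # subnetwork edges are a subset; union over pathways recovers everything
  spec <- network_sim_spec(n_tfs = 80L, seed = 9, base_binding_prob = 0.08)
  sim <- suppressMessages(simulate_network(spec))
  key <- function(e) paste(e$tf_id, e$promoter_id)
  all_sub <- unlist(lapply(unique(sim$promoter_pathways$pathway), function(p) {
    e <- extract_subnetwork(sim, p)$edges
    expect_true(all(key(e) %in% key(sim$edges)))
    key(e)
  }))
  expect_setequal(unique(all_sub), key(sim$edges))
})

test_that("SIF and GraphML exports round-trip the edge set and summary", {
  net <- toy_network()
  sif <- tempfile(fileext = ".sif")
  write_sif(net, sif)
  expect_equal(readLines(sif),
               c("T1\tbinds\tP1", "T1\tbinds\tP2", "T2\tbinds\tP1"))

  one <- suppressMessages(regulatory_network(
    data.frame(tf_id = "T1", promoter_id = "P1")))
  write_sif(one, sif)
  expect_equal(readLines(sif), "T1\tbinds\tP1")

  gml <- tempfile(fileext = ".graphml")
  write_graphml(net, gml)
  back <- suppressMessages(read_graphml(gml))
  key <- function(e) sort(paste(e$tf_id, e$promoter_id))
  expect_equal(key(back$edges), key(net$edges))
  expect_equal(sort(unique(back$promoter_pathways$pathway)), c("A", "B"))

  # 100-edge synthetic round trip preserves the full summary
  spec <- network_sim_spec(n_tfs = 40L, seed = 2, base_binding_prob = 0.05)
  sim <- suppressMessages(simulate_network(spec))
  write_graphml(sim, gml)
  back <- suppressMessages(read_graphml(gml))
  s1 <- network_summary(sim); s2 <- network_summary(back)
  expect_equal(s2$n_edges, s1$n_edges)
  expect_equal(s2$n_tfs, s1$n_tfs)
  expect_equal(s2$promoter_degree_mean, s1$promoter_degree_mean)
  expect_equal(key(back$edges), key(sim$edges))
})

test_that("TSV write -> read is idempotent on edges and annotations", {
  spec <- network_sim_spec(n_tfs = 50L, seed = 4, base_binding_prob = 0.06)
  sim <- suppressMessages(simulate_network(spec))
  d <- tempfile()
  write_network_tables(sim, d)
  back <- suppressMessages(read_edge_list(
    file.path(d, "edges.tsv"),
    pathway_file = file.path(d, "pathways.tsv"),
    family_file = file.path(d, "families.tsv"),
    localization_file = file.path(d, "localization.tsv")))
  key <- function(e) sort(paste(e$tf_id, e$promoter_id))
  expect_equal(key(back$edges), key(sim$edges))
  expect_equal(nrow(back$promoter_pathways), nrow(sim$promoter_pathways))
  expect_equal(sort(back$localization$promoter_id),
               sort(sim$localization$promoter_id))
})
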