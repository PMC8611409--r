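# seeded synthetic-data generators

test_that("binding probability extremes give empty and complete graphs", {
  pw <- data.frame(label = c("A", "B"), n_genes = c(5L, 5L))
  none <- suppressMessages(simulate_network(
    network_sim_spec(n_tfs = 20L, pathways = pw, n_overlap_genes = 0L,
                     base_binding_prob = 0, seed = 1)))
  expect_equal(nrow(none$edges), 0)

  full <- suppressMessages(simulate_network(
    network_sim_spec(n_tfs = 20L, pathways = pw, n_overlap_genes = 0L,
                     base_binding_prob = 1, breadth_sdlog = 0, seed = 1)))
  expect_equal(nrow(full$edges), 20 * 10)
})

test_that("empirical edge density stays within three binomial SDs of the target", {
  spec <- network_sim_spec(n_tfs = 500L,
                           pathways = data.frame(label = c("A", "B"),
                                                 n_genes = c(100L, 100L)),
                           n_overlap_genes = 0L, base_binding_prob = 0.05,
                           breadth_sdlog = 0, seed = 99)
  net <- suppressMessages(simulate_network(spec))
  n_pairs <- 500 * 200
  dens <- nrow(net$edges) / n_pairs
  sd3 <- 3 * sqrt(0.05 * 0.95 / n_pairs)
  expect_lt(abs(dens - 0.05), sd3)
})

test_that("generation is seed-deterministic and seed-sensitive", {
  spec1 <- network_sim_spec(n_tfs = 50L, seed = 5, base_binding_prob = 0.05)
  spec2 <- network_sim_spec(n_tfs = 50L, seed = 6, base_binding_prob = 0.05)
  a <- suppressMessages(simulate_network(spec1))
  b <- suppressMessages(simulate_network(spec1))
  c <- suppressMessages(simulate_network(spec2))
  expect_identical(a$edges, b$edges)
  expect_false(identical(a$edges, c$edges))

  # byte-identical files for the same seed
  d1 <- tempfile(); d2 <- tempfile()
  write_network_tables(a, d1); write_network_tables(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  dg1 <- simulate_deg_sets(1000, sprintf("T%02d", 1:50), 100, 2, seed = 3)
  dg2 <- simulate_deg_sets(1000, sprintf("T%02d", 1:50), 100, 2, seed = 3)
  expect_identical(sort(dg1$genes), sort(dg2$genes))
})

test_that("default spec mirrors the screen's scale", {
  spec <- network_sim_spec(seed = 1)
  expect_equal(spec$n_tfs, 2039L)
  expect_equal(sum(spec$pathways$n_genes), 226L)       # pathway memberships
  expect_equal(nrow(spec$pathways), 12L)
  net <- suppressMessages(simulate_network(spec))
  s <- network_summary(net)
  expect_equal(s$n_promoters + s$n_promoters_hitfree, 224L)  # distinct genes
  # density 0.06 puts the mean promoter degree near the screen's ~125;
  # the sample mean of the log-normal breadth multiplier contributes
  # ~2% relative noise, so allow four of its SDs
  expect_equal(s$promoter_degree_mean, 0.06 * 2039, tolerance = 0.09)
  # two genes belong to two pathways
  memb <- table(net$promoter_pathways$promoter_id)
  expect_equal(sum(memb == 2), 2)
})

test_that("planted coexpression hits the stated population correlation", {
  pw <- data.frame(label = "A", n_genes = 50L)
  net <- suppressMessages(simulate_network(
    network_sim_spec(n_tfs = 50L, pathways = pw, n_overlap_genes = 0L,
                     base_binding_prob = 0.2, seed = 2)))
  e <- net$edges[!duplicated(net$edges$promoter_id), ][1:20, ]

  # rho = 1: deterministic copy, sample r exactly 1
  pl <- data.frame(tf_id = e$tf_id, target_id = e$promoter_id,
                   dataset = "d1", r = 1)
  cs <- coexpr_sim_spec(datasets = data.frame(name = "d1", n_samples = 10L),
                        planted_edges = pl, seed = 2)
  ds <- simulate_coexpression(cs, net)
  m <- ds[[1]]$matrix
  for (j in 1:5) {
    expect_equal(cor(m[e$tf_id[j], ], m[e$promoter_id[j], ]), 1)
  }

  # null edges at n = 40 essentially never reach |r| >= 0.8
  cs0 <- coexpr_sim_spec(datasets = data.frame(name = "d1", n_samples = 40L),
                         seed = 4)
  ds0 <- simulate_coexpression(cs0, net)
  prof <- suppressMessages(edge_correlations(net, ds0))
  expect_lte(mean(abs(prof$r_d1) >= 0.8), 0.01)

  # conflicting planted roles and unknown edges are spec errors
  bad <- data.frame(tf_id = c("X", "Y"), target_id = c("Z", "Z"),
                    dataset = c("d1", "d1"), r = c(0.5, 0.9))
  expect_error(coexpr_sim_spec(planted_edges = bad), "conflicting")
  ghost <- coexpr_sim_spec(planted_edges = data.frame(
    tf_id = "NOPE", target_id = "NADA", dataset = "development", r = 0.5))
  expect_error(simulate_coexpression(ghost, net), "absent")
})

test_that("DEG generator respects the planted overlap odds", {
  targets <- sprintf("T%03d", 1:100)

  # odds ratio 1: overlap at the hypergeometric expectation
  overlaps <- vapply(1:100, function(s) {
    dg <- simulate_deg_sets(2000, targets, 200, 1, seed = s)
    length(intersect(dg$genes, targets))
  }, 0L)
  exp_a <- 200 * 100 / 2000
  sd_a <- sqrt(200 * (100 / 2000) * (1 - 100 / 2000) * (2000 - 200) / 1999)
  expect_lt(abs(mean(overlaps) - exp_a), 3 * sd_a / sqrt(100))

  # near-infinite odds with n_deg >= |targets|: forced saturation
  sat <- simulate_deg_sets(500, targets, 150, 1e6, seed = 1)
  expect_equal(length(intersect(sat$genes, targets)), 100)

  expect_error(simulate_deg_sets(100, targets, 200, 2), "n_deg")
})

test_that("generated files round-trip through the package readers cleanly", {
  spec <- network_sim_spec(n_tfs = 60L, seed = 13, base_binding_prob = 0.06)
  net <- suppressMessages(simulate_network(spec))
  d <- tempfile()
  write_network_tables(net, d)
  expect_no_warning(
    back <- suppressMessages(read_edge_list(
      file.path(d, "edges.tsv"),
      pathway_file = file.path(d, "pathways.tsv"),
      family_file = file.path(d, "families.tsv"),
      localization_file = file.path(d, "localization.tsv"))))
  expect_equal(nrow(back$edges), nrow(net$edges))
})
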