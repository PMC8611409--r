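## Seeded generators emulating the statistical structure of a
## genome-scale Y1H screen: a bipartite binding network over pathways
## with tunable TF breadth and planted pathway-pair sharing, TF-family
## bias toward enzyme-step x compartment gene groups, expression
## compendia with planted dataset-exclusive correlations, and DEG sets
## with a planted target-overlap odds ratio.

# derive an independent RNG seed from (seed, generator name) so adding
# a generator never perturbs the streams of the others
mix_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

#' Specification for a synthetic Y1H binding network
#'
#' Defaults mirror the screen the generators emulate: 2,039 assayed
#' TFs against 224 promoters annotated to 12 metabolic pathways (226
#' pathway memberships — two promoters belong to two pathways), an
#' overall binding density of 0.06, and log-normal per-TF breadth
#' (mean 1) creating promiscuous and narrow TFs.
#'
#' @param n_tfs Number of assayed TFs.
#' @param pathways Data frame `label`, `n_genes` (pathway membership
#'   counts; memberships, not necessarily distinct genes).
#' @param n_overlap_genes Number of genes assigned to two pathways
#'   (reduces the distinct-gene count below the membership total).
#' @param base_binding_prob Baseline per-(TF, promoter) edge probability.
#' @param breadth_sdlog Log-normal sd of the per-TF breadth multiplier;
#'   its meanlog is set to `-breadth_sdlog^2 / 2` so the multiplier has
#'   mean 1.
#' @param planted_pairs `NULL`, or data frame `pathway_a`, `pathway_b`,
#'   `sharing_boost`: a fraction `coreg_frac` of TFs act as shared
#'   regulators of the pair, with their edge probability toward both
#'   pathways multiplied by `sharing_boost`.
#' @param coreg_frac Fraction of TFs acting as shared regulators of
#'   each planted pair.
#' @param planted_family_bias `NULL`, or data frame `family`,
#'   `enzyme_step`, `compartment`, `multiplier`: edge probability of
#'   that family's TFs toward genes of that (step, compartment) group
#'   is multiplied by `multiplier`.
#' @param families Character vector of family labels to assign to TFs.
#' @param step_pathway Label of the pathway whose genes receive enzyme
#'   step and compartment annotation (the TCA-cycle-like pathway).
#' @param seed Integer seed.
#' @return A list of class `network_sim_spec`.
#' @export
network_sim_spec <- function(n_tfs = 2039L,
                             pathways = NULL,
                             n_overlap_genes = 2L,
                             base_binding_prob = 0.06,
                             breadth_sdlog = 0.8,
                             planted_pairs = NULL,
                             coreg_frac = 0.3,
                             planted_family_bias = NULL,
                             families = c("bHLH", "bZIP", "MYB", "AP2-ERF",
                                          "NAC", "WRKY", "C2H2", "GATA",
                                          "LBD", "HD-ZIP", "MADS", "ARF",
                                          "GRAS", "TCP", "Trihelix"),
                             step_pathway = "TCA_cycle",
                             seed = 1L) {
  if (is.null(pathways)) {
    pathways <- data.frame(
      label = c("aliphatic_GSL", "arginine_glycine", "aspartate", "BCAA",
                "cysteine", "glycolysis_gluconeogenesis", "GS_GOGAT",
                "methionine", "pentose_phosphate", "serine", "shikimate",
                "TCA_cycle"),
      n_genes = c(22L, 3L, 9L, 18L, 8L, 64L, 3L, 7L, 25L, 6L, 5L, 56L),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(pathways$n_genes >= 1), n_tfs >= 1,
            base_binding_prob >= 0, base_binding_prob <= 1,
            n_overlap_genes >= 0)
  structure(list(n_tfs = as.integer(n_tfs), pathways = pathways,
                 n_overlap_genes = as.integer(n_overlap_genes),
                 base_binding_prob = base_binding_prob,
                 breadth_sdlog = breadth_sdlog,
                 planted_pairs = planted_pairs, coreg_frac = coreg_frac,
                 planted_family_bias = planted_family_bias,
                 families = families, step_pathway = step_pathway,
                 seed = as.integer(seed)),
            class = "network_sim_spec")
}

#' Simulate a bipartite TF-promoter network with annotations
#'
#' Each potential edge (t, g) is drawn Bernoulli with probability
#' `clip(base * breadth_t * boosts, 0, 1)`, where boosts come from
#' planted pathway-pair sharing and planted family bias (see
#' [network_sim_spec()]). Deterministic for a fixed seed. If clipping
#' occurs everywhere a boost applies, a warning is emitted.
#'
#' @param spec A `network_sim_spec`.
#' @return A `regulatory_network` carrying pathway, family, and
#'   localization annotation tables.
#' @export
simulate_network <- function(spec) {
  stopifnot(inherits(spec, "network_sim_spec"))
  set.seed(mix_seed(spec$seed, "network"))

  pw <- spec$pathways
  n_members <- sum(pw$n_genes)
  n_genes <- n_members - spec$n_overlap_genes
  if (n_genes < max(pw$n_genes)) stop("too many overlap genes for pathway sizes")
  gene_ids <- sprintf("GENE%04d", seq_len(n_genes))

  # fill pathway memberships: first assign each pathway a disjoint block,
  # then re-use the first genes of the largest pathways as overlap genes
  memb <- data.frame(promoter_id = character(0), pathway = character(0),
                     stringsAsFactors = FALSE)
  sizes <- pw$n_genes
  # distinct genes primarily owned per pathway, shaving the overlap off
  # the largest pathways (they re-use genes owned by earlier pathways)
  own <- sizes
  if (spec$n_overlap_genes > 0) {
    shave <- order(sizes, decreasing = TRUE)[seq_len(spec$n_overlap_genes)]
    own[shave] <- own[shave] - 1L
  }
  starts <- cumsum(c(1L, own[-length(own)]))
  for (i in seq_len(nrow(pw))) {
    ids <- gene_ids[seq.int(starts[i], length.out = own[i])]
    memb <- rbind(memb, data.frame(promoter_id = ids, pathway = pw$label[i],
                                   stringsAsFactors = FALSE))
  }
  if (spec$n_overlap_genes > 0) {
    shave <- order(sizes, decreasing = TRUE)[seq_len(spec$n_overlap_genes)]
    for (j in seq_along(shave)) {
      donor <- setdiff(seq_len(nrow(pw)), shave)[j]  # borrow from another pathway
      borrowed <- gene_ids[starts[donor]]
      memb <- rbind(memb, data.frame(promoter_id = borrowed,
                                     pathway = pw$label[shave[j]],
                                     stringsAsFactors = FALSE))
    }
  }

  tf_ids <- sprintf("TF%04d", seq_len(spec$n_tfs))
  fam <- sample(spec$families, spec$n_tfs, replace = TRUE)
  tf_families <- data.frame(tf_id = tf_ids, family = fam,
                            stringsAsFactors = FALSE)

  # enzyme step / compartment annotation for the step pathway
  localization <- NULL
  step_genes <- unique(memb$promoter_id[memb$pathway == spec$step_pathway])
  if (length(step_genes) > 0) {
    steps <- c("PDH_PDC", "CSY", "ACO", "IDH", "OGD", "SCL", "SDH", "FUM", "MDH")
    comps <- c("mitochondrion", "plastid", "peroxisome", "cytosol")
    localization <- data.frame(
      promoter_id = step_genes,
      enzyme_step = sample(steps, length(step_genes), replace = TRUE),
      compartment = sample(comps, length(step_genes), replace = TRUE,
                           prob = c(0.5, 0.2, 0.1, 0.2)),
      evidence = sample(c("consensus_predicted", "experimental"),
                        length(step_genes), replace = TRUE,
                        prob = c(0.8, 0.2)),
      stringsAsFactors = FALSE)
  }

  breadth <- stats::rlnorm(spec$n_tfs,
                           meanlog = -spec$breadth_sdlog^2 / 2,
                           sdlog = spec$breadth_sdlog)

  # per-(TF, gene) probability matrix
  P <- outer(breadth * spec$base_binding_prob, rep(1, n_genes))
  rownames(P) <- tf_ids; colnames(P) <- gene_ids

  genes_of <- function(label) unique(memb$promoter_id[memb$pathway == label])
  if (!is.null(spec$planted_pairs)) {
    pp <- spec$planted_pairs
    for (i in seq_len(nrow(pp))) {
      coreg <- stats::runif(spec$n_tfs) < spec$coreg_frac
      gcols <- union(genes_of(pp$pathway_a[i]), genes_of(pp$pathway_b[i]))
      P[coreg, gcols] <- P[coreg, gcols] * pp$sharing_boost[i]
    }
  }
  if (!is.null(spec$planted_family_bias) && !is.null(localization)) {
    fb <- spec$planted_family_bias
    for (i in seq_len(nrow(fb))) {
      grows <- tf_families$family == fb$family[i]
      gcols <- localization$promoter_id[
        localization$enzyme_step == fb$enzyme_step[i] &
          localization$compartment == fb$compartment[i]]
      if (any(grows) && length(gcols) > 0) {
        P[grows, gcols] <- P[grows, gcols] * fb$multiplier[i]
      }
    }
  }
  if (any(P > 1)) {
    warning(sum(P > 1), " edge probabilities clipped to 1")
    P[P > 1] <- 1
  }

  draw <- matrix(stats::runif(length(P)), nrow(P)) < P
  idx <- which(draw, arr.ind = TRUE)
  edges <- data.frame(tf_id = tf_ids[idx[, 1]],
                      promoter_id = gene_ids[idx[, 2]],
                      stringsAsFactors = FALSE)
  regulatory_network(edges, promoter_pathways = memb,
                     tf_families = tf_families,
                     localization = if (is.null(localization)) NULL else
                       resolve_localization(localization))
}

#' Specification for synthetic expression compendia
#'
#' Defaults emulate five public microarray compendia (development,
#' root, pollen, osmotic, salt) with sample counts in the range such
#' atlases typically have.
#'
#' @param datasets Data frame `name`, `n_samples` (each >= 3).
#' @param planted_edges `NULL`, or data frame `tf_id`, `target_id`,
#'   `dataset`, `r` (|r| <= 1): in that dataset the target profile is
#'   `r * z_tf + sqrt(1 - r^2) * noise`, so the population correlation
#'   is exactly `r` there and 0 in every other dataset.
#' @param seed Integer seed.
#' @return A list of class `coexpr_sim_spec`.
#' @export
coexpr_sim_spec <- function(datasets = data.frame(
                              name = c("development", "root", "pollen",
                                       "osmotic", "salt"),
                              n_samples = c(79L, 60L, 20L, 40L, 40L),
                              stringsAsFactors = FALSE),
                            planted_edges = NULL,
                            seed = 1L) {
  stopifnot(all(datasets$n_samples >= 3))
  if (!is.null(planted_edges)) {
    stopifnot(all(abs(planted_edges$r) <= 1))
    key <- paste(planted_edges$target_id, planted_edges$dataset)
    if (anyDuplicated(key)) {
      stop("a gene is planted in two conflicting roles in one dataset")
    }
  }
  structure(list(datasets = datasets, planted_edges = planted_edges,
                 seed = as.integer(seed)),
            class = "coexpr_sim_spec")
}

#' Simulate expression compendia with planted edge correlations
#'
#' Every network node (TF and promoter gene) gets an independent
#' standard-normal profile per dataset; planted edges overwrite the
#' target profile so its population correlation with the TF equals the
#' planted `r` in the chosen dataset only (see [coexpr_sim_spec()]).
#'
#' @param spec A `coexpr_sim_spec`.
#' @param network The `regulatory_network` whose nodes the matrices
#'   cover; every planted edge must exist in it.
#' @return List of `expression_dataset` objects, one per compendium.
#' @export
simulate_coexpression <- function(spec, network) {
  stopifnot(inherits(spec, "coexpr_sim_spec"),
            inherits(network, "regulatory_network"))
  pe <- spec$planted_edges
  if (!is.null(pe)) {
    key_net <- paste(network$edges$tf_id, network$edges$promoter_id)
    key_pl <- paste(toupper(pe$tf_id), toupper(pe$target_id))
    if (!all(key_pl %in% key_net)) {
      stop("planted edge(s) absent from the network")
    }
  }
  genes <- unique(c(network$edges$tf_id, network$edges$promoter_id))
  out <- vector("list", nrow(spec$datasets))
  for (i in seq_len(nrow(spec$datasets))) {
    dname <- spec$datasets$name[i]
    ns <- spec$datasets$n_samples[i]
    set.seed(mix_seed(spec$seed, paste0("coexpr_", dname)))
    m <- matrix(stats::rnorm(length(genes) * ns), nrow = length(genes),
                dimnames = list(genes, sprintf("%s_s%02d", dname, seq_len(ns))))
    if (!is.null(pe)) {
      here <- pe[pe$dataset == dname, , drop = FALSE]
      for (j in seq_len(nrow(here))) {
        tf <- toupper(here$tf_id[j]); tg <- toupper(here$target_id[j])
        rho <- here$r[j]
        eps <- stats::rnorm(ns)
        m[tg, ] <- rho * m[tf, ] + sqrt(1 - rho^2) * eps
      }
    }
    out[[i]] <- expression_dataset(dname, m)
  }
  out
}

#' Simulate a DEG set with a planted target-overlap odds ratio
#'
#' Draws a differential-expression gene set of fixed size from a
#' universe so that target genes enter with the stated odds relative to
#' non-targets, conditioned on the total DEG count: the target overlap
#' is drawn from Fisher's noncentral hypergeometric distribution with
#' noncentrality `odds_ratio`, then members are sampled uniformly
#' within the target and non-target strata.
#'
#' @param universe_size Number of genes tested for DE.
#' @param targets Character vector of target gene ids (they form the
#'   first stratum of the universe; filler ids `BG#####` complete it).
#' @param n_deg Number of DEGs to draw (`<= universe_size`).
#' @param odds_ratio Planted inclusion odds ratio (> 0; 1 = null).
#' @param seed Integer seed.
#' @param contrast_id Label for the resulting `deg_set`.
#' @return A `deg_set`.
#' @export
simulate_deg_sets <- function(universe_size, targets, n_deg, odds_ratio,
                              seed = 1L, contrast_id = "synthetic_contrast") {
  targets <- unique(toupper(trimws(targets)))
  K <- length(targets)
  stopifnot(n_deg <= universe_size, odds_ratio > 0, K <= universe_size)
  set.seed(mix_seed(seed, "deg"))
  N <- universe_size; n <- n_deg
  lo <- max(0L, n + K - N); hi <- min(n, K)
  if (lo > hi) stop("infeasible DEG spec: empty overlap support")
  supp <- lo:hi
  logw <- lchoose(K, supp) + lchoose(N - K, n - supp) + supp * log(odds_ratio)
  pr <- exp(logw - max(logw)); pr <- pr / sum(pr)
  a <- supp[sample.int(length(supp), 1L, prob = pr)]

  filler <- sprintf("BG%05d", seq_len(N - K))
  deg_genes <- c(sample(targets, a),
                 sample(filler, n - a))
  deg_set(contrast_id, deg_genes, universe = c(targets, filler))
}

#' Write a simulated network and its annotations as TSV files
#'
#' Emits the same formats [read_edge_list()] consumes: `edges.tsv`,
#' `pathways.tsv`, `families.tsv`, and (when present)
#' `localization.tsv`, into `dir`.
#'
#' @param network A `regulatory_network`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_network_tables <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                         quote = FALSE, row.names = FALSE)
  w(network$edges, "edges.tsv")
  if (!is.null(network$promoter_pathways)) w(network$promoter_pathways, "pathways.tsv")
  if (!is.null(network$tf_families)) w(network$tf_families, "families.tsv")
  if (!is.null(network$localization)) w(network$localization, "localization.tsv")
  invisible(dir)
}
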