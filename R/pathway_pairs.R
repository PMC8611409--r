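#' Pairwise pathway TF-sharing enrichment
#'
#' For every unordered pair of annotated pathways, tests whether the two
#' pathways share more distinct TFs than expected, given the total
#' number of TFs screened. The 2x2 table for pathways A and B is
#' `a = |A intersect B|`, `b = |A \ B|`, `c = |B \ A|`,
#' `d = universe - |A union B|`, where A and B are the distinct TF sets
#' binding each pathway's promoters. A one-tailed (greater) Fisher's
#' exact test is applied per pair and p-values are adjusted jointly
#' across all `choose(P, 2)` pairs.
#'
#' @param network A `regulatory_network` with pathway annotation on at
#'   least two pathways.
#' @param universe Number of TFs screened (background). Defaults to the
#'   full assayed TF collection when `tf_families` covers it, otherwise
#'   must be supplied; must be at least the size of the union of all
#'   pathway TF sets.
#' @param adjust_method `"BH"` (default) or `"Holm"`.
#' @return Data frame, one row per unordered pair: `pathway_a`,
#'   `pathway_b`, `n_a`, `n_b`, `n_shared`, `universe`, `odds_ratio`,
#'   `p_raw`, `p_adj`, `regional_score` (`p_adj / odds_ratio`).
#' @export
pairwise_pathway_sharing <- function(network, universe = NULL,
                                     adjust_method = c("BH", "Holm")) {
  adjust_method <- match.arg(adjust_method)
  sets <- pathway_tf_sets(network)
  if (length(sets) < 2L) {
    warning("fewer than two annotated pathways; nothing to compare")
    return(data.frame())
  }
  all_tfs <- unique(unlist(sets))
  if (is.null(universe)) {
    if (!is.null(network$tf_families)) {
      universe <- length(unique(network$tf_families$tf_id))
    } else {
      stop("supply `universe` (number of TFs screened)")
    }
  }
  if (universe < length(all_tfs)) {
    stop("universe (", universe, ") smaller than the union of pathway TF sets (",
         length(all_tfs), ")")
  }

  labs <- sort(names(sets))
  pairs <- utils::combn(labs, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(j) {
    pa <- pairs[1, j]; pb <- pairs[2, j]
    A <- sets[[pa]]; B <- sets[[pb]]
    a <- length(intersect(A, B))
    b <- length(A) - a
    c <- length(B) - a
    d <- universe - (a + b + c)
    fe <- fisher_exact(c(a, b, c, d), "greater")
    data.frame(pathway_a = pa, pathway_b = pb,
               n_a = length(A), n_b = length(B), n_shared = a,
               universe = universe,
               odds_ratio = fe$odds_ratio, p_raw = fe$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p_raw, adjust_method)
  out$regional_score <- out$p_adj / out$odds_ratio
  attr(out, "adjust_method") <- adjust_method
  out
}

#' Regional-enrichment ranking of a focal pathway's partners
#'
#' Ranks the partner pathways of one focal pathway by the score
#' `p_adj / odds_ratio` (ascending: the smallest score is the most
#' enriched partner). Ties are broken by larger shared-TF count, then
#' lexicographic partner label. A zero odds ratio yields an infinite
#' score (ranked last); an undefined odds ratio excludes the pair with a
#' warning.
#'
#' @param results Output of [pairwise_pathway_sharing()].
#' @param focal_pathway Pathway label whose partners are ranked.
#' @return Data frame with `partner`, `n_shared`, `odds_ratio`, `p_adj`,
#'   `regional_score`, `rank`, ordered by rank.
#' @export
regional_enrichment_rank <- function(results, focal_pathway) {
  hit <- results$pathway_a == focal_pathway | results$pathway_b == focal_pathway
  if (!any(hit)) stop("no pairs involve pathway: ", focal_pathway)
  r <- results[hit, , drop = FALSE]
  r$partner <- ifelse(r$pathway_a == focal_pathway, r$pathway_b, r$pathway_a)

  undef <- is.na(r$odds_ratio)
  if (any(undef)) {
    warning("excluding ", sum(undef), " pair(s) with undefined odds ratio")
    r <- r[!undef, , drop = FALSE]
  }
  score <- ifelse(r$odds_ratio == 0, Inf, r$p_adj / r$odds_ratio)
  r$regional_score <- score
  o <- order(score, -r$n_shared, r$partner)
  r <- r[o, c("partner", "n_shared", "odds_ratio", "p_adj",
              "regional_score"), drop = FALSE]
  r$rank <- seq_len(nrow(r))
  rownames(r) <- NULL
  r
}

#' Export the pathway-pathway TF-sharing graph as GraphML
#'
#' Companion visualisation output: one node per pathway (attribute
#' `n_tfs`, the pathway's distinct TF count) and one edge per pair
#' (attribute `n_shared`), mirroring the pathway cross-talk figures such
#' networks are drawn from.
#'
#' @param results Output of [pairwise_pathway_sharing()].
#' @param network The `regulatory_network` the results came from.
#' @param path Output GraphML path.
#' @export
write_pathway_graph <- function(results, network, path) {
  sets <- pathway_tf_sets(network)
  nodes <- data.frame(name = names(sets),
                      n_tfs = vapply(sets, length, 0L),
                      stringsAsFactors = FALSE)
  el <- results[, c("pathway_a", "pathway_b", "n_shared")]
  g <- igraph::graph_from_data_frame(el, directed = FALSE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
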