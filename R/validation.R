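#' Construct a differential-expression gene set
#'
#' One contrast's significant genes (e.g. an inducible-TF line,
#' dexamethasone vs mock) together with the universe of genes actually
#' tested for differential expression — the correct Fisher background,
#' which is the expressed/tested gene set rather than the whole genome.
#'
#' @param contrast_id Label for the contrast.
#' @param genes Character vector of significant gene identifiers.
#' @param universe Character vector of all genes tested; must contain
#'   `genes`.
#' @param direction `"up"`, `"down"`, or `"any"`.
#' @return Object of class `deg_set`.
#' @export
deg_set <- function(contrast_id, genes, universe,
                    direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  genes <- unique(toupper(trimws(genes)))
  universe <- unique(toupper(trimws(universe)))
  if (length(universe) == 0) stop("empty universe")
  out <- setdiff(genes, universe)
  if (length(out) > 0) stop("DEG(s) outside the universe: ",
                            paste(utils::head(out, 5), collapse = ", "))
  structure(list(contrast_id = contrast_id, genes = genes,
                 universe = universe, direction = direction),
            class = "deg_set")
}

#' Read a per-contrast DEG table and universe list
#'
#' DEG TSV columns: `gene_id`, `direction` (`up`/`down`), `significant`
#' (logical or 0/1). The universe file is one gene id per line.
#'
#' @param contrast_id Label.
#' @param deg_file DEG TSV path.
#' @param universe_file Universe path.
#' @param direction Keep `"up"`, `"down"`, or `"any"` significant genes.
#' @return A `deg_set`.
#' @export
read_deg_set <- function(contrast_id, deg_file, universe_file,
                         direction = c("any", "up", "down")) {
  direction <- match.arg(direction)
  d <- utils::read.delim(deg_file, sep = "\t", header = TRUE,
                         check.names = FALSE)
  sig <- as.logical(d$significant) | d$significant == 1
  if (direction != "any") sig <- sig & d$direction == direction
  uni <- readLines(universe_file)
  uni <- uni[nzchar(uni)]
  deg_set(contrast_id, d$gene_id[sig], uni, direction)
}

# shared contingency construction: target-set membership x DEG membership
deg_contingency <- function(deg, targets) {
  stopifnot(inherits(deg, "deg_set"))
  targets <- unique(toupper(trimws(targets)))
  dropped <- setdiff(targets, deg$universe)
  if (length(dropped) > 0) {
    warning(length(dropped), " target(s) outside the DE universe dropped")
    targets <- intersect(targets, deg$universe)
  }
  if (length(targets) == 0) stop("no targets remain within the universe")
  a <- length(intersect(targets, deg$genes))
  b <- length(targets) - a
  c <- length(deg$genes) - a
  d <- length(deg$universe) - a - b - c
  list(a = a, b = b, c = c, d = d, targets = targets)
}

#' Enrichment of network-predicted targets among DEGs
#'
#' One-tailed (greater) Fisher's exact test of the overlap between a
#' TF's yeast one-hybrid target set and the genes differentially
#' expressed when that TF is induced. Promoters are named by their
#' downstream gene, so target identifiers compare directly with DEG
#' gene identifiers.
#'
#' @param deg A `deg_set`.
#' @param targets Character vector of target gene identifiers; targets
#'   outside the DE universe are dropped with a warning.
#' @return One-row data frame: contrast, counts `a, b, c, d`,
#'   `odds_ratio`, `p_raw`.
#' @export
target_deg_enrichment <- function(deg, targets) {
  ct <- deg_contingency(deg, targets)
  fe <- fisher_exact(c(ct$a, ct$b, ct$c, ct$d), "greater")
  data.frame(contrast_id = deg$contrast_id, n_targets = ct$a + ct$b,
             n_deg = ct$a + ct$c,
             a = ct$a, b = ct$b, c = ct$c, d = ct$d,
             odds_ratio = fe$odds_ratio, p_raw = fe$p_raw,
             stringsAsFactors = FALSE)
}

#' Enrichment of a pathway's genes among DEGs
#'
#' Same construction as [target_deg_enrichment()] with a pathway's gene
#' set as the target set, additionally reporting the recovered fraction
#' `a / |pathway genes in universe|` (the "x% of pathway genes
#' differentially expressed" statistic).
#'
#' @param deg A `deg_set`.
#' @param pathway_genes Character vector of the pathway's gene ids.
#' @return One-row data frame as [target_deg_enrichment()] plus
#'   `recovered_fraction`.
#' @export
pathway_deg_enrichment <- function(deg, pathway_genes) {
  res <- target_deg_enrichment(deg, pathway_genes)
  res$recovered_fraction <- res$a / (res$a + res$b)
  res
}

#' Compartment-specific DEG enrichment within a pathway
#'
#' Restricted to one pathway's genes, asks per compartment whether the
#' compartment's isoforms are over- or under-represented among the
#' differentially expressed pathway genes (two-sided Fisher's exact
#' test: compartment membership x DEG membership within the pathway).
#' Both raw and BH-adjusted significance flags are reported.
#'
#' @param deg A `deg_set`.
#' @param pathway_genes_by_compartment Named list: compartment label ->
#'   character vector of the pathway's gene ids in that compartment
#'   (e.g. from [resolve_localization()]); empty compartments are
#'   skipped with a warning.
#' @param alpha Significance level (default 0.05).
#' @return Data frame, one row per compartment: counts, `odds_ratio`,
#'   `p_raw`, `p_adj`, `significant_raw`, `significant_adj`.
#' @export
compartment_deg_enrichment <- function(deg, pathway_genes_by_compartment,
                                       alpha = 0.05) {
  stopifnot(inherits(deg, "deg_set"))
  comps <- pathway_genes_by_compartment
  empty <- vapply(comps, length, 0L) == 0L
  if (any(empty)) {
    warning("skipping empty compartment(s): ",
            paste(names(comps)[empty], collapse = ", "))
    comps <- comps[!empty]
  }
  all_path <- unique(toupper(trimws(unlist(comps))))
  all_path <- intersect(all_path, deg$universe)
  if (length(all_path) == 0) stop("no pathway genes within the universe")
  deg_path <- intersect(all_path, deg$genes)

  rows <- lapply(names(comps), function(cp) {
    g <- intersect(unique(toupper(trimws(comps[[cp]]))), all_path)
    a <- length(intersect(g, deg_path))
    b <- length(g) - a
    c <- length(deg_path) - a
    d <- length(all_path) - a - b - c
    fe <- fisher_exact(c(a, b, c, d), "two_sided")
    data.frame(compartment = cp, a = a, b = b, c = c, d = d,
               odds_ratio = fe$odds_ratio, p_raw = fe$p_raw,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p_raw, "BH")
  out$significant_raw <- out$p_raw < alpha
  out$significant_adj <- out$p_adj < alpha
  out
}
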