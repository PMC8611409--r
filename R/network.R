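#' Construct a bipartite TF-promoter regulatory network
#'
#' The central container of the package: a deduplicated set of directed
#' TF -> promoter binding edges (as detected in a yeast one-hybrid
#' screen) together with optional annotation tables. Identifiers are
#' uppercased at construction (AGI gene codes are case-insensitive by
#' convention), and bipartiteness is enforced: no identifier may appear
#' both as a TF and as a promoter.
#'
#' @param edges Data frame with character columns `tf_id` and
#'   `promoter_id`, one row per detected interaction. Duplicate rows are
#'   collapsed (the screen is presence/absence); the number collapsed is
#'   reported via `message()`.
#' @param promoter_pathways Optional data frame `promoter_id`, `pathway`
#'   (long format; a promoter annotated to several pathways has several
#'   rows). May include screened promoters with no detected edges.
#' @param tf_families Optional data frame `tf_id`, `family`. May include
#'   the full assayed TF collection, not just TFs with edges.
#' @param localization Optional resolved localization table
#'   `promoter_id`, `enzyme_step`, `compartment` (see
#'   [resolve_localization()]).
#' @return An object of class `regulatory_network`.
#' @export
regulatory_network <- function(edges, promoter_pathways = NULL,
                               tf_families = NULL, localization = NULL) {
  req <- c("tf_id", "promoter_id")
  if (!all(req %in% names(edges))) {
    stop("edge table must have columns tf_id and promoter_id")
  }
  edges <- data.frame(tf_id = toupper(trimws(as.character(edges$tf_id))),
                      promoter_id = toupper(trimws(as.character(edges$promoter_id))),
                      stringsAsFactors = FALSE)
  if (any(edges$tf_id == "") || any(edges$promoter_id == "")) {
    stop("empty identifiers in edge table")
  }
  n_in <- nrow(edges)
  edges <- unique(edges)
  n_dup <- n_in - nrow(edges)
  if (n_dup > 0) message(n_dup, " duplicate edge(s) collapsed (", n_in,
                         " rows read, ", nrow(edges), " unique edges)")

  overlap <- intersect(unique(edges$tf_id), unique(edges$promoter_id))
  if (length(overlap) > 0) {
    stop("bipartiteness violation: identifier(s) used as both TF and promoter: ",
         paste(utils::head(overlap, 5), collapse = ", "))
  }

  norm_tab <- function(tab, idcol) {
    if (is.null(tab)) return(NULL)
    tab <- as.data.frame(tab, stringsAsFactors = FALSE)
    tab[[idcol]] <- toupper(trimws(as.character(tab[[idcol]])))
    unique(tab)
  }
  promoter_pathways <- norm_tab(promoter_pathways, "promoter_id")
  tf_families <- norm_tab(tf_families, "tf_id")
  localization <- norm_tab(localization, "promoter_id")

  structure(list(edges = edges,
                 promoter_pathways = promoter_pathways,
                 tf_families = tf_families,
                 localization = localization),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("regulatory_network:", nrow(x$edges), "edges |",
      length(unique(x$edges$tf_id)), "TFs |",
      length(unique(x$edges$promoter_id)), "promoters\n")
  if (!is.null(x$promoter_pathways)) {
    cat("  pathways:", length(unique(x$promoter_pathways$pathway)),
        "over", length(unique(x$promoter_pathways$promoter_id)),
        "annotated promoters\n")
  }
  invisible(x)
}

#' Read a TF-promoter edge list and optional annotations from TSV files
#'
#' The edge list is a tab-separated file with a header containing at
#' least `tf_id` and `promoter_id` columns. An empty file (header only)
#' yields an empty network. Annotation files follow the same layout as
#' the corresponding arguments of [regulatory_network()].
#'
#' @param path Path to the edge-list TSV.
#' @param pathway_file,family_file,localization_file Optional annotation
#'   TSV paths (`promoter_id<TAB>pathway`, `tf_id<TAB>family`, and
#'   `promoter_id<TAB>enzyme_step<TAB>compartment<TAB>evidence`).
#' @return A `regulatory_network`.
#' @export
read_edge_list <- function(path, pathway_file = NULL, family_file = NULL,
                           localization_file = NULL) {
  read_tsv0 <- function(p) utils::read.delim(p, sep = "\t", header = TRUE,
                                             colClasses = "character",
                                             check.names = FALSE)
  edges <- read_tsv0(path)
  if (!all(c("tf_id", "promoter_id") %in% names(edges))) {
    stop("edge list ", path, " lacks required columns tf_id, promoter_id")
  }
  pw <- if (!is.null(pathway_file)) read_tsv0(pathway_file) else NULL
  fam <- if (!is.null(family_file)) read_tsv0(family_file) else NULL
  loc <- if (!is.null(localization_file)) {
    raw <- read_tsv0(localization_file)
    if ("evidence" %in% names(raw)) resolve_localization(raw) else raw
  } else NULL
  regulatory_network(edges, promoter_pathways = pw, tf_families = fam,
                     localization = loc)
}

#' Summarise network topology
#'
#' Counts are taken over detected nodes: `n_promoters` counts only
#' promoters with at least one interaction; screened but hit-free
#' promoters (present in the pathway annotation, absent from the edge
#' set) are reported separately as `n_promoters_hitfree`.
#'
#' @param network A `regulatory_network`.
#' @return A list of class `network_summary`: `n_edges`, `n_tfs`,
#'   `n_promoters`, `n_promoters_hitfree`, `promoter_degree_min/max/mean`,
#'   and `tf_pathway_multiplicity` (named vector: number of distinct
#'   pathways spanned -> number of TFs) when pathway annotation exists.
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  if (nrow(e) == 0L) {
    out <- list(n_edges = 0L, n_tfs = 0L, n_promoters = 0L,
                n_promoters_hitfree = 0L,
                promoter_degree_min = 0L, promoter_degree_max = 0L,
                promoter_degree_mean = 0,
                tf_pathway_multiplicity = NULL)
    class(out) <- "network_summary"
    return(out)
  }
  deg <- table(e$promoter_id)
  hitfree <- 0L
  mult <- NULL
  if (!is.null(network$promoter_pathways)) {
    screened <- unique(network$promoter_pathways$promoter_id)
    hitfree <- length(setdiff(screened, e$promoter_id))
    k <- tf_pathway_breadth(network)
    mult <- table(factor(k, levels = sort(unique(k))))
    storage.mode(mult) <- "integer"
  }
  out <- list(n_edges = nrow(e),
              n_tfs = length(unique(e$tf_id)),
              n_promoters = length(deg),
              n_promoters_hitfree = hitfree,
              promoter_degree_min = as.integer(min(deg)),
              promoter_degree_max = as.integer(max(deg)),
              promoter_degree_mean = mean(deg),
              tf_pathway_multiplicity = mult)
  class(out) <- "network_summary"
  out
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("%d interactions between %d TFs and %d promoters\n",
              x$n_edges, x$n_tfs, x$n_promoters))
  if (x$n_edges > 0) {
    cat(sprintf("per-promoter degree %d-%d, mean %.1f; %d screened promoter(s) hit-free\n",
                x$promoter_degree_min, x$promoter_degree_max,
                x$promoter_degree_mean, x$n_promoters_hitfree))
  }
  invisible(x)
}

# number of distinct pathways spanned by each detected TF (named integer)
tf_pathway_breadth <- function(network) {
  pw <- network$promoter_pathways
  if (is.null(pw)) stop("network has no pathway annotation")
  e <- network$edges
  missing_anno <- setdiff(unique(e$promoter_id), unique(pw$promoter_id))
  if (length(missing_anno) > 0) {
    stop("promoter(s) without pathway annotation: ",
         paste(utils::head(missing_anno, 5), collapse = ", "))
  }
  m <- merge(e, pw, by = "promoter_id")
  tapply(m$pathway, m$tf_id, function(p) length(unique(p)))
}

#' Fraction of TFs whose bound promoters span at least k pathways
#'
#' The denominator is the set of TFs with at least one detected edge.
#' Every promoter in the network must carry pathway annotation.
#'
#' @param network A `regulatory_network` with pathway annotation.
#' @param k_min Minimum number of distinct pathways (default 2).
#' @return Fraction in `[0, 1]`; 0 for an empty network.
#' @export
pathway_multiplicity_fraction <- function(network, k_min = 2L) {
  stopifnot(inherits(network, "regulatory_network"), k_min >= 1)
  if (nrow(network$edges) == 0L) return(0)
  k <- tf_pathway_breadth(network)
  mean(k >= k_min)
}

#' Restrict a network to one pathway's promoters
#'
#' Keeps edges whose promoter is annotated to `pathway`; annotation
#' tables are restricted to the touched nodes.
#'
#' @param network A `regulatory_network` with pathway annotation.
#' @param pathway Pathway label (must exist in the annotation).
#' @return A `regulatory_network` subnetwork.
#' @export
extract_subnetwork <- function(network, pathway) {
  stopifnot(inherits(network, "regulatory_network"))
  pw <- network$promoter_pathways
  if (is.null(pw)) stop("network has no pathway annotation")
  if (!pathway %in% pw$pathway) stop("unknown pathway: ", pathway)
  keep_prom <- unique(pw$promoter_id[pw$pathway == pathway])
  e <- network$edges[network$edges$promoter_id %in% keep_prom, , drop = FALSE]
  keep_tf <- unique(e$tf_id)
  sub <- regulatory_network(
    e,
    promoter_pathways = pw[pw$promoter_id %in% unique(e$promoter_id), , drop = FALSE],
    tf_families = if (is.null(network$tf_families)) NULL else
      network$tf_families[network$tf_families$tf_id %in% keep_tf, , drop = FALSE],
    localization = if (is.null(network$localization)) NULL else
      network$localization[network$localization$promoter_id %in% unique(e$promoter_id), , drop = FALSE])
  sub
}

#' Distinct TF sets per pathway
#'
#' A TF belongs to a pathway's set if it binds at least one promoter
#' annotated to that pathway; a promoter in several pathways contributes
#' its TFs to each (sets, not multisets).
#'
#' @param network A `regulatory_network` with pathway annotation.
#' @return Named list: pathway -> character vector of TF ids.
#' @export
pathway_tf_sets <- function(network) {
  stopifnot(inherits(network, "regulatory_network"))
  pw <- network$promoter_pathways
  if (is.null(pw)) stop("network has no pathway annotation")
  m <- merge(network$edges, pw, by = "promoter_id")
  lapply(split(m$tf_id, m$pathway), unique)
}

#' Export a network as a Cytoscape SIF file
#'
#' One line per edge: `tf_id<TAB>binds<TAB>promoter_id`.
#'
#' @param network A non-empty `regulatory_network`.
#' @param path Output path.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  if (nrow(network$edges) == 0L) stop("refusing to export an empty network")
  lines <- paste(network$edges$tf_id, "binds", network$edges$promoter_id,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Nodes carry a `role` attribute (`TF` or `promoter`); promoters carry
#' their pathway annotation (semicolon-joined) and TFs their family,
#' where available. A round trip through [read_graphml()] reproduces the
#' edge set.
#'
#' @param network A non-empty `regulatory_network`.
#' @param path Output path.
#' @export
write_graphml <- function(network, path) {
  stopifnot(inherits(network, "regulatory_network"))
  e <- network$edges
  if (nrow(e) == 0L) stop("refusing to export an empty network")
  tfs <- unique(e$tf_id)
  proms <- unique(e$promoter_id)
  nodes <- data.frame(name = c(tfs, proms),
                      role = c(rep("TF", length(tfs)),
                               rep("promoter", length(proms))),
                      stringsAsFactors = FALSE)
  nodes$pathway <- ""
  if (!is.null(network$promoter_pathways)) {
    pp <- vapply(split(network$promoter_pathways$pathway,
                       network$promoter_pathways$promoter_id),
                 function(p) paste(sort(unique(p)), collapse = ";"), "")
    idx <- match(nodes$name, names(pp))
    nodes$pathway[!is.na(idx)] <- pp[idx[!is.na(idx)]]
  }
  nodes$family <- ""
  if (!is.null(network$tf_families)) {
    fm <- network$tf_families
    idx <- match(nodes$name, fm$tf_id)
    nodes$family[!is.na(idx)] <- fm$family[idx[!is.na(idx)]]
  }
  g <- igraph::graph_from_data_frame(e, directed = TRUE, vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML file written by [write_graphml()]
#'
#' @param path GraphML path.
#' @return A `regulatory_network` with pathway and family annotation
#'   recovered from the node attributes.
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  el <- igraph::as_data_frame(g, what = "edges")
  v <- igraph::as_data_frame(g, what = "vertices")
  edges <- data.frame(tf_id = el$from, promoter_id = el$to,
                      stringsAsFactors = FALSE)
  pw <- NULL
  if ("pathway" %in% names(v)) {
    pv <- v[v$role == "promoter" & nzchar(v$pathway), , drop = FALSE]
    if (nrow(pv) > 0) {
      pw <- do.call(rbind, lapply(seq_len(nrow(pv)), function(i) {
        data.frame(promoter_id = pv$name[i],
                   pathway = strsplit(pv$pathway[i], ";", fixed = TRUE)[[1]],
                   stringsAsFactors = FALSE)
      }))
    }
  }
  fam <- NULL
  if ("family" %in% names(v)) {
    fv <- v[v$role == "TF" & nzchar(v$family), , drop = FALSE]
    if (nrow(fv) > 0) {
      fam <- data.frame(tf_id = fv$name, family = fv$family,
                        stringsAsFactors = FALSE)
    }
  }
  regulatory_network(edges, promoter_pathways = pw, tf_families = fam)
}
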