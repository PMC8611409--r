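#' Resolve subcellular localization with experimental precedence
#'
#' A gene may carry several localization rows (e.g. a consensus
#' prediction from a localization database and a literature-reported
#' experimental determination). Experimental evidence overrides the
#' consensus prediction; conflicting experimental rows are an error.
#'
#' @param records Data frame with columns `promoter_id`, `enzyme_step`,
#'   `compartment`, `evidence` (`"consensus_predicted"` or
#'   `"experimental"`).
#' @return Data frame with one row per gene: `promoter_id`,
#'   `enzyme_step`, `compartment`, `evidence` (the winning evidence
#'   class).
#' @export
resolve_localization <- function(records) {
  req <- c("promoter_id", "enzyme_step", "compartment", "evidence")
  if (!all(req %in% names(records))) {
    stop("localization table needs columns: ", paste(req, collapse = ", "))
  }
  bad <- !records$evidence %in% c("consensus_predicted", "experimental")
  if (any(bad)) stop("unknown evidence value(s): ",
                     paste(unique(records$evidence[bad]), collapse = ", "))
  records$promoter_id <- toupper(trimws(records$promoter_id))
  per_gene <- split(records, records$promoter_id)
  rows <- lapply(per_gene, function(g) {
    exp_rows <- g[g$evidence == "experimental", , drop = FALSE]
    if (nrow(exp_rows) > 0) {
      if (length(unique(exp_rows$compartment)) > 1 ||
          length(unique(exp_rows$enzyme_step)) > 1) {
        stop("conflicting experimental localization for gene ",
             g$promoter_id[1])
      }
      exp_rows[1, req]
    } else {
      if (length(unique(g$compartment)) > 1) {
        # ambiguous consensus: keep the first after sorting for determinism
        g <- g[order(g$compartment), , drop = FALSE]
      }
      g[1, req]
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' TF-family enrichment by enzyme step and subcellular compartment
#'
#' Within a pathway subnetwork whose genes carry enzyme-step and
#' compartment labels, tests every (family, enzyme step, compartment)
#' triple for enrichment of that family's TFs among the TFs binding that
#' gene group. For family F and gene group (E, C):
#' `a` = distinct TFs of F binding at least one (E, C) gene,
#' `b` = remaining TFs of F in the assayed collection,
#' `c` = non-F TFs binding the group, `d` = remaining non-F TFs.
#' Two-sided Fisher's exact test, Holm-adjusted jointly across all
#' triples with at least one annotated gene.
#'
#' @param subnetwork A `regulatory_network` whose promoters all carry
#'   resolved localization (enzyme_step + compartment).
#' @param families Data frame `tf_id`, `family` for the full assayed TF
#'   collection (the denominator universe); defaults to the
#'   subnetwork's `tf_families` table.
#' @param localization Resolved localization table; defaults to the
#'   subnetwork's `localization`.
#' @param alpha Significance level on the adjusted p (default 0.05).
#' @return Data frame, one row per (family, enzyme_step, compartment):
#'   counts `a, b, c, d`, `pct_family_binding` (a / family TFs present
#'   in the subnetwork), `odds_ratio`, `p_raw`, `p_adj`, `significant`.
#' @export
family_compartment_enrichment <- function(subnetwork, families = NULL,
                                          localization = NULL,
                                          alpha = 0.05) {
  stopifnot(inherits(subnetwork, "regulatory_network"))
  if (is.null(families)) families <- subnetwork$tf_families
  if (is.null(localization)) localization <- subnetwork$localization
  if (is.null(families)) stop("TF family table required")
  if (is.null(localization)) stop("localization table required")

  e <- subnetwork$edges
  un_loc <- setdiff(unique(e$promoter_id), localization$promoter_id)
  if (length(un_loc) > 0) {
    stop("subnetwork promoter(s) without localization: ",
         paste(utils::head(un_loc, 5), collapse = ", "))
  }
  collection <- unique(families$tf_id)
  n_collection <- length(collection)
  fam_of <- stats::setNames(families$family, families$tf_id)

  known_fams <- sort(unique(families$family))
  # TFs of the subnetwork absent from the collection table would break
  # the margins; they are excluded with a warning
  stray <- setdiff(unique(e$tf_id), collection)
  if (length(stray) > 0) {
    warning(length(stray), " subnetwork TF(s) absent from the family table; excluded")
    e <- e[e$tf_id %in% collection, , drop = FALSE]
  }

  loc <- localization[localization$promoter_id %in% unique(e$promoter_id), ,
                      drop = FALSE]
  groups <- unique(loc[, c("enzyme_step", "compartment")])
  if (nrow(groups) == 0L) stop("no annotated gene groups in subnetwork")

  rows <- list()
  for (i in seq_len(nrow(groups))) {
    E <- groups$enzyme_step[i]; C <- groups$compartment[i]
    grp_genes <- loc$promoter_id[loc$enzyme_step == E & loc$compartment == C]
    binders <- unique(e$tf_id[e$promoter_id %in% grp_genes])
    for (F in known_fams) {
      fam_tfs <- collection[fam_of[collection] == F]
      a <- length(intersect(binders, fam_tfs))
      b <- length(fam_tfs) - a
      c <- length(binders) - a
      d <- n_collection - length(fam_tfs) - c
      fe <- fisher_exact(c(a, b, c, d), "two_sided")
      fam_in_sub <- length(intersect(fam_tfs, unique(e$tf_id)))
      rows[[length(rows) + 1L]] <- data.frame(
        family = F, enzyme_step = E, compartment = C,
        a = a, b = b, c = c, d = d,
        pct_family_binding = if (fam_in_sub > 0) a / fam_in_sub else NA_real_,
        odds_ratio = fe$odds_ratio, p_raw = fe$p_raw,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- adjust_pvalues(out$p_raw, "Holm")
  out$significant <- out$p_adj < alpha
  attr(out, "universe") <- n_collection
  attr(out, "construction") <- "family-membership x binding-status margins"
  out
}
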