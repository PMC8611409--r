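#' Construct an expression dataset
#'
#' A named, gene-by-sample matrix of normalized expression values (one
#' compendium, e.g. a development atlas or a stress series). Gene rows
#' must be unique (probe-to-gene collapsing happens upstream) and at
#' least three samples are required for correlation.
#'
#' @param name Dataset label.
#' @param matrix Numeric matrix, rownames = gene identifiers, columns =
#'   samples.
#' @return Object of class `expression_dataset`.
#' @export
expression_dataset <- function(name, matrix) {
  if (is.null(rownames(matrix))) stop("expression matrix needs gene rownames")
  if (anyDuplicated(rownames(matrix))) {
    stop("duplicate gene rows in dataset ", name, "; collapse upstream")
  }
  if (ncol(matrix) < 3L) stop("dataset ", name, " has fewer than 3 samples")
  rownames(matrix) <- toupper(trimws(rownames(matrix)))
  structure(list(name = name, matrix = matrix), class = "expression_dataset")
}

#' Read an expression dataset from TSV
#'
#' First column = gene identifier, remaining columns = samples.
#'
#' @param name Dataset label.
#' @param path TSV path.
#' @return An `expression_dataset`.
#' @export
read_expression_tsv <- function(name, path) {
  d <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- as.character(d[[1]])
  expression_dataset(name, m)
}

#' Pearson correlation with degenerate-input flagging
#'
#' Plain Pearson product-moment correlation; returns `NA` (a
#' missing-flag, not an error) when either vector is constant, so that
#' flat expression profiles never masquerade as correlated.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` for degenerate input.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = "pearson")
}

#' Per-edge correlation profiles across expression compendia
#'
#' For every network edge, computes the TF-target Pearson correlation
#' in each dataset. The correlation is a missing-flag (`NA`, never a
#' zero fill) when either gene is absent from the dataset or has a
#' constant profile. Computed-vs-missing counts per dataset are
#' reported via `message()`.
#'
#' @param network A `regulatory_network`.
#' @param datasets List of `expression_dataset` objects.
#' @return Data frame: `tf_id`, `target_id`, one numeric `r_<name>`
#'   column and one integer `n_<name>` sample-count column per dataset.
#' @export
edge_correlations <- function(network, datasets) {
  stopifnot(inherits(network, "regulatory_network"), length(datasets) > 0)
  e <- network$edges
  out <- data.frame(tf_id = e$tf_id, target_id = e$promoter_id,
                    stringsAsFactors = FALSE)
  for (ds in datasets) {
    stopifnot(inherits(ds, "expression_dataset"))
    m <- ds$matrix
    r <- rep(NA_real_, nrow(e))
    present <- e$tf_id %in% rownames(m) & e$promoter_id %in% rownames(m)
    if (any(present)) {
      idx <- which(present)
      tf_m <- m[e$tf_id[idx], , drop = FALSE]
      tg_m <- m[e$promoter_id[idx], , drop = FALSE]
      sd_tf <- apply(tf_m, 1, stats::sd)
      sd_tg <- apply(tg_m, 1, stats::sd)
      ok <- sd_tf > 0 & sd_tg > 0
      if (any(ok)) {
        xc <- sweep(tf_m[ok, , drop = FALSE], 1, rowMeans(tf_m[ok, , drop = FALSE]))
        yc <- sweep(tg_m[ok, , drop = FALSE], 1, rowMeans(tg_m[ok, , drop = FALSE]))
        r[idx[ok]] <- rowSums(xc * yc) /
          sqrt(rowSums(xc^2) * rowSums(yc^2))
      }
    }
    out[[paste0("r_", ds$name)]] <- r
    out[[paste0("n_", ds$name)]] <- ifelse(present, ncol(m), 0L)
    message("dataset ", ds$name, ": ", sum(!is.na(r)), " computed, ",
            sum(is.na(r)), " missing")
  }
  out
}

#' Classify edges by the datasets in which they are co-expressed
#'
#' An edge "passes" in a dataset when `|r| >= threshold` (a missing
#' correlation never passes). Edges are grouped by their exact pass-set
#' (Venn cells over datasets), yielding the conditionality structure:
#' how many edges are co-expressed anywhere, exclusively in one
#' dataset, in exactly two, and so on.
#'
#' @param profiles Output of [edge_correlations()].
#' @param threshold Absolute-correlation cutoff in `(0, 1]`
#'   (default 0.8; the comparison is `>=`).
#' @return List of class `conditionality_partition`: `per_edge` (data
#'   frame with `tf_id`, `target_id`, `pass_set` string, `n_pass`),
#'   `venn_counts` (named vector: sorted `+`-joined dataset subset ->
#'   edge count, passing edges only), `n_pass_any`, `n_exclusive`,
#'   `n_by_k` (named vector: number of datasets passed -> edges),
#'   `threshold`, `datasets`.
#' @export
classify_conditionality <- function(profiles, threshold = 0.8) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  rcols <- grep("^r_", names(profiles), value = TRUE)
  if (length(rcols) == 0) stop("no r_<dataset> columns in profiles")
  dnames <- sub("^r_", "", rcols)
  rmat <- as.matrix(profiles[, rcols, drop = FALSE])
  pass <- !is.na(rmat) & abs(rmat) >= threshold

  pass_set <- apply(pass, 1, function(z) paste(sort(dnames[z]), collapse = "+"))
  n_pass <- rowSums(pass)
  per_edge <- data.frame(tf_id = profiles$tf_id,
                         target_id = profiles$target_id,
                         pass_set = pass_set, n_pass = n_pass,
                         stringsAsFactors = FALSE)
  passing <- per_edge[per_edge$n_pass > 0, , drop = FALSE]
  venn <- table(passing$pass_set)
  venn_counts <- stats::setNames(as.integer(venn), names(venn))
  n_by_k <- table(factor(passing$n_pass, levels = seq_along(dnames)))
  structure(list(per_edge = per_edge,
                 venn_counts = venn_counts,
                 n_pass_any = nrow(passing),
                 n_exclusive = sum(passing$n_pass == 1L),
                 n_by_k = stats::setNames(as.integer(n_by_k), names(n_by_k)),
                 threshold = threshold,
                 datasets = dnames),
            class = "conditionality_partition")
}

#' @export
print.conditionality_partition <- function(x, ...) {
  cat(sprintf("conditionality partition over %d dataset(s), |r| >= %.2f\n",
              length(x$datasets), x$threshold))
  cat(sprintf("  %d edge(s) pass in >= 1 dataset; %d exclusive to one\n",
              x$n_pass_any, x$n_exclusive))
  for (k in names(x$n_by_k)) {
    cat(sprintf("  in exactly %s dataset(s): %d\n", k, x$n_by_k[[k]]))
  }
  invisible(x)
}
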