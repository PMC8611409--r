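#' Hypergeometric probability mass function
#'
#' Probability of drawing exactly `k` marked items in a sample of size `n`
#' from an urn of `N` items of which `K` are marked:
#' `choose(K, k) * choose(N - K, n - k) / choose(N, n)`.
#' Computed in log space so it remains accurate for universes of tens of
#' thousands of genes or TFs.
#'
#' @param k Number of marked items drawn (vectorised).
#' @param N Universe size.
#' @param K Number of marked items in the universe.
#' @param n Sample size.
#' @return Probability (0 for `k` outside the support).
#' @examples
#' hypergeom_pmf(4, N = 8, K = 4, n = 4)  # 1/70
#' @export
hypergeom_pmf <- function(k, N, K, n) {
  stopifnot(N >= 0, K >= 0, n >= 0, K <= N, n <= N)
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  out <- numeric(length(k))
  ok <- k >= lo & k <= hi
  if (any(ok)) {
    kk <- k[ok]
    out[ok] <- exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n))
  }
  out
}

#' Build a 2x2 contingency table
#'
#' Cell layout follows the enrichment convention used throughout the
#' package: `a` in-group successes, `b` in-group failures, `c` out-group
#' successes, `d` out-group failures.
#'
#' @param a,b,c,d Non-negative integer cell counts; the total must be > 0.
#' @return An object of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("contingency cells must be non-negative counts")
  }
  if (sum(cells) <= 0) stop("contingency table must have positive total")
  structure(as.list(cells), class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(c("in_group", "out_group"),
                              c("success", "failure")))
  print(m)
  invisible(x)
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact test of association with fixed margins. The one-tailed
#' (`"greater"`) p-value is `P(X >= a)` under the hypergeometric
#' distribution induced by the table margins. The two-sided p-value uses
#' the minimum-likelihood rule: the sum of `P(X = x)` over all `x` in the
#' support whose point probability does not exceed that of the observed
#' table, up to a relative tolerance of `1 + 1e-7` (the convention of
#' common exact-test implementations, kept for reproducibility of
#' adjusted-p comparisons).
#'
#' The reported odds ratio is the unconditional sample odds ratio
#' `(a*d)/(b*c)` — not the conditional maximum-likelihood estimate —
#' because downstream rank scores only require a monotone, reproducible
#' enrichment measure. It is `Inf` when `b*c == 0` and `a*d > 0`, and
#' `NA` when both products are zero (no discrimination possible).
#'
#' @param table A `contingency_2x2`, or a length-4 vector `(a, b, c, d)`.
#' @param sidedness `"greater"` or `"two_sided"`.
#' @param haldane If `TRUE`, add 0.5 to every cell when computing the
#'   odds ratio only (never the p-value).
#' @return A one-row data frame with columns `a, b, c, d, odds_ratio,
#'   p_raw, p_adj, sidedness, adjust_method`; `p_adj` is `NA` until an
#'   adjustment is applied across a family of tests.
#' @examples
#' fisher_exact(c(3, 1, 1, 3), "greater")$p_raw  # 17/70
#' @export
fisher_exact <- function(table, sidedness = c("greater", "two_sided"),
                         haldane = FALSE) {
  sidedness <- match.arg(sidedness)
  if (!inherits(table, "contingency_2x2")) {
    stopifnot(length(table) == 4)
    table <- contingency_2x2(table[[1]], table[[2]], table[[3]], table[[4]])
  }
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  N <- a + b + c + d
  K <- a + c        # successes in universe
  n <- a + b        # in-group size
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  support <- lo:hi
  pmf <- hypergeom_pmf(support, N = N, K = K, n = n)

  if (sidedness == "greater") {
    p <- sum(pmf[support >= a])
  } else {
    p_obs <- pmf[match(a, support)]
    p <- sum(pmf[pmf <= p_obs * (1 + 1e-7)])
  }
  p <- min(1, max(0, p))

  if (haldane) {
    or <- ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else {
    ad <- a * d; bc <- b * c
    or <- if (bc == 0 && ad == 0) NA_real_ else if (bc == 0) Inf else ad / bc
  }

  data.frame(a = a, b = b, c = c, d = d,
             odds_ratio = or, p_raw = p, p_adj = NA_real_,
             sidedness = sidedness, adjust_method = "none",
             stringsAsFactors = FALSE)
}

#' Multiple-testing adjustment of p-values
#'
#' Step-up Benjamini-Hochberg (`"BH"`, controls the false discovery
#' rate) and step-down Holm (`"Holm"`, controls the family-wise error
#' rate), both returned in the input order and capped at 1. Written out
#' explicitly so that every downstream enrichment stage shares a single,
#' auditable adjustment path.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"`, `"Holm"`, or `"none"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' adjust_pvalues(c(0.01, 0.02, 0.03), "BH")    # all 0.03
#' adjust_pvalues(c(0.01, 0.04), "Holm")        # 0.02, 0.04
#' @export
adjust_pvalues <- function(p, method = c("BH", "Holm", "none")) {
  method <- match.arg(method)
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (method == "none" || m == 1L) return(p)

  if (method == "BH") {
    o <- order(p, decreasing = TRUE)       # largest first for cummin
    ro <- order(o)
    i <- m:1L                              # ranks of the sorted sequence
    adj <- pmin(1, cummin(m / i * p[o]))[ro]
  } else {
    o <- order(p)                          # smallest first for cummax
    ro <- order(o)
    adj <- pmin(1, cummax((m - seq_len(m) + 1L) * p[o]))[ro]
  }
  adj
}
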