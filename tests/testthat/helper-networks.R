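# small fixture networks built in code

toy_network <- function() {
  # T1 binds P1 (pathway A) and P2 (pathway B); T2 binds P1 only
  suppressMessages(regulatory_network(
    data.frame(tf_id = c("T1", "T1", "T2"),
               promoter_id = c("P1", "P2", "P1")),
    promoter_pathways = data.frame(promoter_id = c("P1", "P2"),
                                   pathway = c("A", "B"))))
}

# brute-force one-tailed Fisher p by direct pmf summation (independent
# of fisher_exact's internal path)
brute_greater <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  supp <- max(0, n + K - N):min(n, K)
  pmf <- exp(lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n))
  sum(pmf[supp >= a])
}

brute_two_sided <- function(a, b, c, d) {
  N <- a + b + c + d; K <- a + c; n <- a + b
  supp <- max(0, n + K - N):min(n, K)
  pmf <- exp(lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n))
  sum(pmf[pmf <= pmf[match(a, supp)] * (1 + 1e-7)])
}

random_table <- function(max_total = 60) {
  repeat {
    cells <- as.integer(rmultinom(1, sample(4:max_total, 1),
                                  prob = runif(4) + 0.05))
    if (sum(cells) > 0) return(cells)
  }
}
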