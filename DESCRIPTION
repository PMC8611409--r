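Package: y1hnet
Title: Bipartite Transcription Factor-Promoter Network Analysis for Yeast One-Hybrid Screens
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of genome-scale yeast one-hybrid (Y1H) protein-DNA
    interaction screens as bipartite transcription factor (TF)-promoter
    networks. Provides network construction and topology summaries,
    exact hypergeometric/Fisher enrichment tests with
    Benjamini-Hochberg and Holm multiple-testing correction, pairwise
    pathway TF-sharing enrichment with a regional-enrichment rank
    score, TF-family by enzyme-step by subcellular-compartment
    enrichment, per-edge conditional co-expression classification
    across expression compendia, enrichment of network targets in
    differentially expressed gene sets, and seeded synthetic-data
    generators that emulate the statistical structure of such screens
    for fully reproducible benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
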