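Package: mirlink
Title: Integrated miRNA-mRNA Differential Expression and Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrated small-RNA and mRNA sequencing analysis pipeline for
    two-group designs: negative-binomial Wald differential expression with
    median-of-ratios normalization and trend-shrunk dispersion estimates, FPKM
    expression filtering, unification of validated and predicted miRNA target
    tables, extraction of anti-correlated miRNA-mRNA pairs, bipartite
    interaction-network construction with degree and betweenness centrality and
    core-node selection, and hypergeometric over-representation analysis of
    gene lists against GMT collections with Benjamini-Hochberg correction. A
    seeded synthetic-data generator with planted miRNA-target repression
    structure makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    DESeq2,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
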