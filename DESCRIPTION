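Package: vascross
Title: Cross-Species Concordance Analysis of Vascular Aging Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding which animal model best mirrors human
    vascular aging at the level of signaling pathways. From young/old
    single-cell expression matrices in several species the package computes
    Wilcoxon rank-sum differential expression with Bonferroni correction,
    from-scratch pre-ranked gene set enrichment (permutation NES),
    ortholog-mediated cross-species gene and pathway concordance labels
    (same-trend "SM" versus divergent "DE"), animal-model recommendations,
    trimean/Hill ligand-receptor communication probabilities with
    old-vs-young differential networks, betweenness-centrality hub genes on
    a protein-protein interaction graph, and gradient-boosting transcription
    factor to target importance with regulon assembly. A negative-binomial
    synthetic-study generator with planted ground truth supports end-to-end
    recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    methods,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
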