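Package: regulonr
Title: Regulon Discovery from Co-Expression and Cis-Regulatory Motif Clustering in Bacteria
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for predicting condition-specific regulons in
    bacterial genomes by combining transcriptomics with comparative genomics.
    Starting from a genome sequence, an operon table and a paired control/treatment
    expression matrix, the pipeline calls differentially expressed genes with an
    exact Wilcoxon signed-rank test, groups operons into co-expression modules by
    hierarchical clustering, discovers fixed-width cis-regulatory motifs in operon
    promoter regions against a whole-genome background, clusters the pooled motifs
    by position-weight-matrix similarity using threshold (Kruskal-style) clustering,
    annotates the resulting regulons against a transcription-factor binding-site
    library and a target proteome, and assembles a typed gene regulatory network.
    A synthetic-data generator with planted ground truth supports calibration and
    recovery benchmarking without any external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
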