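Package: regqtl
Title: Bayesian QTL Window Mapping, eQTL Scans, and SNP-Gene Regulation Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for mapping trait-associated QTL windows with
    Bayes B/C mixture-prior whole-genome regression (Gibbs sampling with a
    point-mass-at-zero prior on SNP effects, 1-Mb window decomposition of
    genetic variance), scanning cis/trans expression QTL by per-pair linear
    regression with covariate adjustment and class-wise Benjamini-Hochberg FDR,
    intersecting the two maps, LD-pruning to tag-SNPs, and exporting signed
    SNP-to-gene regulation networks. Ships variant QC and positional merging
    for genotype panels plus transcribed variants, CPM/log2 expression
    preparation, and a synthetic-data generator with ground truth for
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    igraph,
    vcfR,
    edgeR,
    stats,
    utils,
    tools,
    Rcpp,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
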