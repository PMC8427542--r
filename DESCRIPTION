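Package: phagelife
Title: Phage Lifestyle Classification for Metagenomic Fragments with
    Convolutional Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies metagenomic and metavirome DNA fragments as derived
    from virulent or temperate bacteriophages. Sequences are one-hot encoded
    and scored by length-stratified one-dimensional convolutional neural
    networks (one model per fragment-length group), trained with Adam on
    binary cross-entropy. Includes MetaSim-style fragment simulation from
    labelled genomes, a Markov-chain synthetic genome generator for
    self-contained benchmarks, genome-level cross-validation with
    sensitivity/specificity/accuracy and rank-based AUC, length-aware
    prediction routing with long-sequence splitting and an adjustable
    uncertainty cut-off, and per-sample temperate-proportion cohort
    comparison by the two-sided Wilcoxon rank-sum test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
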