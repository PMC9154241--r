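Package: chromfeat
Title: Continuous Chromatin State Feature Annotation with Non-Negative
    State Space Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotates a genome with real-valued chromatin state features
    from a set of epigenomic signal tracks (fold-enrichment ChIP-seq,
    DNase-seq and similar), using a linear-Gaussian state space model over
    200 bp bins trained by expectation-maximization. Latent features and the
    emission matrix can be constrained non-negative via projection and an
    active-set method of Lagrange multipliers, with an optional sum-to-one
    variant. Includes annotation-quality evaluations (gene-expression and
    enhancer-activity regressions, per-feature ROC against genomic
    elements), a generative-model simulator and toy-genome builder for
    fully offline testing, and command-line entry points for
    train/annotate/evaluate/simulate workflows.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomeInfoDb,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
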