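Package: lmmdge
Title: Linear Mixed Model Differential Expression Analysis for Quantitative Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Differential gene expression (DGE) analysis of continuous
    quantitative traits from bulk RNA-seq count data. Implements
    median-of-ratios size-factor normalization with log2 transformation,
    per-gene association testing by a linear mixed model whose random effect
    uses a sample-sample relatedness matrix derived from all gene
    expressions (REML estimation of the variance-component ratio via
    eigendecomposition, Wald tests), plus three comparison engines: standard
    linear regression, Huber robust regression fitted by iteratively
    reweighted least squares, and voom precision weights with an
    empirical-Bayes moderated t-test on a median-dichotomized trait.
    Includes genomic-control calibration diagnostics (lambda, QQ, volcano
    and Manhattan tables) and a negative-binomial count simulator with a
    pervasive latent confounder for studying false-positive calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    BiocGenerics,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    limma,
    MASS,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
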