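Package: cisetest
Title: Cis-SNP Set Testing for Gene Expression with Linear Mixed Models
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Variance-component testing of cis-SNP sets against gene
    expression with a one-component linear mixed model. Provides restricted
    maximum likelihood (REML) estimation through the spectral representation,
    an exact simulation-based likelihood ratio test (eLRT) for the boundary
    null hypothesis of zero cis-genetic variance, a fast approximate test
    (aLRT) based on a point-mass/scaled chi-square mixture null, a
    variance-component score test, best linear unbiased estimation (BLUE) of
    cis-SNP effects, genome scans for eGenes with Bonferroni control,
    enrichment of eGenes over approximately independent LD blocks, gene-level
    association of genetically imputed expression in an independent cohort
    (PrediXcan-style), and a synthetic-data module for type-I-error and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    methods,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    SummarizedExperiment,
    VariantAnnotation
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
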