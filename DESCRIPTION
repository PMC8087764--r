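Package: cushaw
Title: Population-Genomic Analysis of Squash Domestication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for population-genomic analyses of crop domestication in
    Cucurbita, built around the cushaw pumpkin (Cucurbita argyrosperma) study
    system: a structured-coalescent simulator for wild/domesticated/outgroup
    sampling designs, SNP filtering (minor-allele frequency, missingness,
    Hardy-Weinberg exact test, windowed linkage-disequilibrium pruning),
    diversity and structure statistics (nucleotide diversity, Weir-Cockerham
    F(ST) with bootstrap confidence intervals, genotype PCA), site-frequency-
    spectrum based comparison of competing domestication scenarios by
    simulated composite likelihood and AIC, a three-test selection-scan
    consensus (hierarchical F-model MCMC with an environmental covariate,
    PCA-based Mahalanobis outlier detection, latent-factor ridge association),
    ABBA-BABA introgression statistics with block-jackknife significance and
    admixture-fraction estimation, and dual-caller structural-variant
    consensus with gene-level enrichment tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    MASS,
    vcfR,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    coda,
    rtracklayer
Config/testthat/edition: 3
RoxygenNote: 7.3.3
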