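Package: sirelink
Title: Cross-System Phenotype Prediction from Microbiome and Genomic Data
    in Sire-Linked Pig Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools to study how faecal microbiome composition and SNP
    genotypes predict growth and carcass phenotypes across two swine
    production systems (a purebred nucleus herd and a crossbred terminal
    herd) that share only their founding sires. Implements a synthetic
    generator for sire-linked populations with genotypes, multi-time-point
    OTU count tables and phenotypes of known generative structure;
    quality control and compositional preprocessing (SNP call-rate/MAF
    filters, sparse-OTU filtering, rarefaction, centered-log-ratio
    transform); a Gibbs sampler for Bayesian Ridge Regression with fixed
    factors, grouped random factors and dense omic coefficient blocks;
    sire-stratified, sire-family-left-out and permutation-null
    cross-population cross-validation; and accuracy/null-distribution
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    vegan,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'sirelink-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'methods.R'
    'simulate.R'
    'preprocess.R'
    'brr.R'
    'crossval.R'
    'evaluate.R'
    'io.R'
    'report.R'
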