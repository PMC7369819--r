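Package: methgout
Title: Promoter Methylation, meQTL and Causal Inference Pipeline for Gouty
    Inflammation
Version: 1.0.0
Authors@R:
    person("Hsin-Ying", "Lin", email = "hylin.epigenetics@gmail.com",
           role = c("aut", "cre"))
Description: A multi-stage inference pipeline that identifies promoter CpG
    methylation sites specifically associated with gouty inflammation and
    classifies each candidate as genetically independent, methylation-mediated,
    or genetically confounded. Implements promoter-restricted epigenome-wide
    association on methylation beta values with covariate and cell-subset
    adjustment and Benjamini-Hochberg false discovery control, reference-based
    blood cell-type deconvolution by constrained least-squares projection,
    cis methylation quantitative trait locus and disease scans, a seeded
    four-component causal inference test for variant-methylation-disease
    triples, three-group urate contrasts, metabolic-trait specificity screens,
    co-methylation analysis of neighbouring probes, and a seeded synthetic
    cohort generator with configurable causal structures for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    Rcpp,
    stats,
    tools,
    utils,
    vcfR,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
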