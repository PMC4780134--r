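Package: castenet
Title: Comparative Caste-Associated Gene Co-Expression Network Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Cross-species analysis of queen-worker caste transcriptomes in
    social insects. Builds an orthogroup-by-sample expression matrix (TMM
    normalization, transcript aggregation, missingness filtering), infers a
    weighted gene co-expression network with topological-overlap module
    detection and module eigengenes, associates eigengenes with caste and
    species-level traits through a Bayesian phylogenetic mixed model sampled
    by MCMC, runs per-species negative-binomial differential expression with
    cross-species overlap resampling, regresses dN/dS on connectivity and
    expression, and provides hypergeometric enrichment and module
    preservation statistics. Includes a synthetic-data generator with planted
    modules and phylogenetically structured effects for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    MASS,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
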