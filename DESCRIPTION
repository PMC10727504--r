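Package: mscflow
Title: Multispecies Coalescent Inference of Species Trees and Introgression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale tools for studying speciation histories with gene
    flow under the multispecies coalescent (MSC). The package represents
    species trees and introgression networks (MSC-I) with their parameters
    (divergence times tau, population sizes theta, introgression
    probabilities phi, migration rates M), simulates gene trees and JC69
    sequence alignments under MSC, MSC-I and MSC-with-migration models,
    computes exact pruning likelihoods and coalescent gene-tree densities,
    runs blockwise Bayesian MCMC for species-tree posteriors and fixed-
    network parameter estimation with marginal likelihoods by thermodynamic
    integration, fits maximum-likelihood isolation-with-migration models to
    species triplets with likelihood-ratio tests, extracts filtered
    multilocus alignments from genotype calls, and tabulates blockwise
    results with absolute-time calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    seqinr,
    vcfR,
    IRanges,
    pracma,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
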