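Package: gmyc
Title: Species Delimitation from Single-Locus Gene Trees with the
    Generalized Mixed Yule Coalescent
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Delimits putative species on an ultrametric single-locus gene
    tree by fitting a mixed model that combines a generalized Yule branching
    process between species with independent neutral coalescent processes
    within species. Provides the null (single-population) and mixed
    waiting-interval likelihoods with rate-scaling exponents, closed-form
    profile rate estimators, the single-threshold model scan, a split/fuse
    multiple-threshold heuristic search, likelihood-ratio and simulation
    tests against the null model, and AIC-weight based confidence sets,
    per-node support values and model-averaged parameter estimates. A
    companion multispecies-coalescent simulator generates gene trees within
    Yule or birth-death species trees under constant, growing or declining
    populations, log-normally varying population sizes and several sampling
    schemes, and an evaluation harness computes delimitation accuracy and
    error rates over replicated simulations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
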