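Package: phyloCCM
Title: Community Coevolution Model for Phylogenetic Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Joint modelling of correlated gain and loss of binary traits
    (phylogenetic profiles) on a rooted phylogeny. Each gene in a community
    evolves as a two-state continuous-time Markov chain whose instantaneous
    transition rate depends on the current presence states of the other
    community members, through an intrinsic rate and a symmetric matrix of
    pairwise interaction coefficients. Provides pruning-based likelihood
    computation, l2-penalized maximum-likelihood fitting with Wald tests,
    Hessian and parametric-bootstrap standard errors, a condition-number rule
    for choosing the penalty, an exact event-driven simulator with benchmark
    scenario generators, phylogeny-aware baseline scores (Jaccard, Hamming,
    mutual information, hypergeometric, run- and clade-adjusted variants, and
    Pagel's correlated-evolution likelihood-ratio test), and an all-versus-all
    pairwise scanning pipeline with Benjamini-Yekutieli correction, network
    thresholding and triplet-based conditional-independence pruning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
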