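Package: chromdrift
Title: State-Dependent Chromosome Number Evolution on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a continuous-time Markov model of haploid chromosome
    number evolution in which fusion and fission rates depend on a binary
    hyperstate (for example small versus large geographic range, a proxy
    for effective population size). Provides Felsenstein pruning
    likelihoods over the combined count-by-hyperstate space, Bayesian
    slice-sampling MCMC over posterior tree distributions, the rate
    difference statistic with highest-posterior-density intervals,
    tip-rate reconstruction from marginal ancestral states, a greedy
    branch rate-bin heterogeneity scan, spherical convex-hull range-size
    estimation from occurrence coordinates, and exact stochastic
    simulation of karyotype and binary-trait evolution for adequacy and
    false-positive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    geosphere,
    stats,
    grDevices,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
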