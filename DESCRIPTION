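Package: mixcv
Title: Bayesian Cross-Validation of Amino Acid Profile Mixture Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits amino acid replacement models spanning Poisson or
    general-time-reversible exchangeabilities combined with a single
    frequency profile, empirical profile mixtures with free weights, free
    finite profile mixtures, or a Dirichlet-process profile mixture (the
    CAT family), with optional discrete-gamma rate variation, by Markov
    chain Monte Carlo on a fixed tree topology.  Model fit is compared by
    fivefold Bayesian cross-validation over alignment columns, reported
    relative to a reference model together with per-replicate best-model
    tallies.  Includes readers and writers for FASTA, PHYLIP, Newick,
    profile tables and MCMC traces, and a simulator for alignments with
    across-site profile and rate heterogeneity.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    seqinr,
    Rcpp,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
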