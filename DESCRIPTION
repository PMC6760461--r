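Package: hyperlps
Type: Package
Title: Hyperbrain Network Analysis of Dyadic EEG Source Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for dyadic EEG hyperscanning at the source
    level: lagged phase synchronization between three-dimensional current
    density time series of cortical regions of interest, binarization of
    connectivity into intra-brain, inter-brain and hyperbrain networks by a
    median plus median-absolute-deviation threshold, global graph measures
    normalized against degree-preserving random and lattice surrogate
    ensembles, hemispheric and regional asymmetry indices, and session-level
    mixed-design analyses of variance with partial eta squared and observed
    power. Includes a seeded simulator of coupled narrowband dipole sources
    for two interacting brains so that every stage can be validated against
    known lagged-coupling ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tibble,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
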