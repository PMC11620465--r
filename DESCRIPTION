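Package: qifnet
Title: Ephaptic and Synaptic Spiking Networks with Multiscale-Entropy
    Complexity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates networks of quadratic integrate-and-fire neurons
    coupled through a small-world synaptic layer and an all-to-all,
    distance-weighted ephaptic (electric field) layer. Provides forward-Euler
    integration of the network equations with a threshold/reset spike rule,
    local field potential extraction, sample entropy and multiscale-entropy
    analysis with an integrated complexity score, paired ephaptic-on versus
    ephaptic-off experiment sweeps with Wilcoxon rank-sum comparisons, and
    deterministic signal generators for validating the entropy estimators.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
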