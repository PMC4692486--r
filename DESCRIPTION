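Package: hopscape
Title: Multistable Connectome-Based Hopfield Networks and Their Attractor Landscapes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for graded-response Hopfield
    networks coupled through a structural connectome. Implements three model
    variants (static-local, static-global and dynamic-global activation
    thresholds), deterministic and stochastic Euler integration, random
    sampling-based reconstruction of the fixed-point attractor landscape,
    energy and entropy characterization of attractor sets, inclusion-match
    agglomerative clustering of binary activation patterns, degree-preserving
    connectome randomization, and sliding-window functional connectivity
    dynamics on hemodynamically convolved (Balloon/Windkessel) signals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
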