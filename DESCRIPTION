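Package: spikedbn
Title: Effective Connectivity from Ensemble Spike Trains via Dynamic
    Bayesian Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying experience-dependent plasticity in
    simultaneously recorded neural ensembles.  Simulates stimulus-evoked
    spike trains from networks with planted, lagged, signed connectivity
    (inhomogeneous Bernoulli/Poisson model at 1-ms resolution), infers
    effective connectivity with dynamic Bayesian networks scored by the
    Bayesian Dirichlet equivalent (BDe) metric and searched by simulated
    annealing with add/delete/reverse moves, and quantifies plasticity as
    changes in a PCA-derived network-similarity statistic, in pre-synaptic
    convergence, and in classical single-neuron response metrics (evoked
    spike count and first-spike latency).  Includes an exhaustive-search
    oracle for small networks and a config-driven pipeline emulating a
    whisker-pairing experiment across three recording sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
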