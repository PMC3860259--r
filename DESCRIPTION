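Package: bnpval
Title: Boolean Network Inference, Intervention, and Controllability-Based Validation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Gene regulatory network analysis in the Boolean network with
    perturbation (BNp) framework. Builds exact transition probability matrices
    and steady-state distributions for BNps and probabilistic Boolean networks,
    derives optimal stationary intervention policies by maximal steady-state
    alteration (MSSA), infers networks from binary state-transition time series
    with five algorithms (REVEAL, Best-Fit, and BIC-, MDL-, and
    universal-MDL-penalized search), and validates inference by three
    semi-metrics: adjacency Hamming distance, steady-state L1 distance, and a
    controllability distance measuring the loss of achievable steady-state
    shift when a policy designed on the inferred network is applied to the true
    one. Ships the 10-gene metastatic melanoma WNT5A network and a seeded
    random-ensemble experiment harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
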