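Package: selfother
Title: Self-Other Generalisation Models for Social Value Orientation Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for simulating and fitting Bayesian self-other
    generalisation models of a three-phase social value orientation
    paradigm (the Intentions Game). Provides a constricted Fehr-Schmidt
    utility over a discretised preference grid, random-preference choice
    likelihoods, trial-by-trial Bayesian belief updating about a partner,
    precision-weighted social contagion of preferences, a lattice of four
    models crossing self-insertion with contagion (plus a one-dimensional
    relative-reward variant), partner matching to a target choice
    dissimilarity, MAP fitting with Laplace model evidence, hierarchical
    random-effects model comparison with protected exceedance
    probabilities, and simulate-and-refit parameter and model recovery
    driven by a synthetic cohort generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
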