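Package: tcgsurprise
Title: Surprise-Based Message Planning and Model-Based Analysis for the
    Tacit Communication Game
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generative modelling of novel non-verbal communication in the
    Tacit Communication Game (TCG): a Sender plans a trajectory on a grid
    board that signals the Receiver's hidden goal by maximizing
    information-theoretic (Shannon) surprise against movement-kinetic and
    goal-orientation priors, discounted by the points remaining after the
    shortest route through both goals.  The package implements the planner
    and its two degenerate variants (state-prior-only and
    movement-prior-only), trajectory likelihoods, hierarchical
    empirical-Bayes parameter estimation with Laplace-approximated model
    evidence, random-effects model comparison (model frequencies and
    protected exceedance probabilities), model-free behavioral indices
    (message types and profiles), posterior predictive checks with default
    JZS Bayes factors, synthetic cohort and physiological-epoch generators,
    and model-informed analyses of step-locked pupillometry and EEG-like
    data including cluster-based permutation correction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
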