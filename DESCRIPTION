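Package: chainsim
Title: Simulation of Behaviour-Sequence Learning Through Conditioned
    Reinforcement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the 'chaining' model of associative learning, in
    which an agent learns state-behaviour values and conditioned
    (secondary) reinforcement values over finite stochastic task
    environments, choosing behaviours by a softmax rule compatible with
    the matching law. Provides an exact Bellman policy-evaluation and
    value-iteration oracle to certify near-optimality, constructors for
    classic task models (behaviour chains, self-control, primate nut
    cracking, misbehaviour, delayed-cue discriminations with perceptual
    aliasing), backward- and forward-chaining training protocols,
    learning-time scaling experiments, a seeded random-task generator
    for property testing, and task-specification file IO with a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
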