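Package: pitsbn
Title: Latent-Cause Sigmoid Belief Network Simulation of Pavlovian-Instrumental Transfer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates the three-phase Pavlovian-instrumental transfer (PIT)
    paradigm with a latent-cause sigmoid belief network. Binary conditioning
    trials (sounds, levers, foods, lever pressing) are generated under a
    configurable random-ratio reinforcement schedule; link weights and node
    biases are learned by random-walk Metropolis MCMC against an exact
    marginal likelihood that enumerates all latent-cause configurations; and
    the trained network is evaluated at test to decompose instrumental vigor
    into efficacy (probability of the action's own outcome) and utility
    (value of additional predicted outcomes), reproducing specific PIT,
    general PIT, PIT inhibition, outcome devaluation, and the model's
    predictions about continuous reinforcement and context overlap.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
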