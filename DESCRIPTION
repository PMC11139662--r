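Package: fedinf
Title: Federated Active Inference and Belief Sharing in Agent Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator for ensembles of discrete-state active-inference agents
    that share beliefs through communicative outcome channels. Implements
    variational message passing for partially observed Markov decision
    processes with Dirichlet-parameterised likelihoods, expected-free-energy
    planning (risk, ambiguity and novelty), soft-broadcast belief sharing with
    sensory attenuation, gated Dirichlet learning with Bayes-optimal
    forgetting, and Bayesian model reduction for structure learning. Ships the
    three-sentinel surveillance world and protocols for belief-sharing
    demonstrations, language acquisition and transgenerational transmission,
    de novo language emergence, and supervised structure learning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
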