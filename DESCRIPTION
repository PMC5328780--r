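Package: stickwalk
Title: Neuromechanical Model of Inter-Leg Coordination in Stick Insect Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a network model of three ipsilateral stick-insect legs.
    Each leg carries three local control circuits (protractor-retractor,
    levator-depressor, extensor-flexor) built from half-center central pattern
    generators of nonspiking neurons, premotor interneurons, motoneurons and
    antagonistic muscle pairs driving the joint angles alpha, beta and gamma.
    Sensory-gated inhibitory pathways from each posterior levator-depressor
    system onto the next anterior one produce tripod and tetrapod coordination
    patterns and the transition between them. The package implements three
    reversible mechanisms for decoupling a leg from the coordination chain
    (perturbing the intersegmental synapse, changing the central drive to the
    levator-depressor CPG, and inhibiting or disinhibiting premotor
    interneurons), phase-sweep experiments over decoupling onset times, and a
    gait-analysis stage that turns angle time series into step events, periods,
    phase lags and coordination-pattern labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
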