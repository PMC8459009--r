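Package: CortexColumn
Title: Cortical Column Spiking-Network Simulation and Persistent-Activity Assay
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation of a three-layer, five-cell-type neocortical column of
    2,000 adaptive exponential integrate-and-fire (aEIF) neurons coupled by
    conductance-based AMPA, GABA-A and NMDA synapses with Tsodyks-Markram
    short-term plasticity and transmission delays. Binary 30x30 images are
    encoded as pulse currents onto layer 2/3 pyramidal cells and decoded from
    the spiking response, yielding a persistent-activity (working-memory) assay
    with spike-density, excited-neuron-ratio and signal-transfer-accuracy
    metrics, repeat-level summaries (mean, SEM, one-way ANOVA), scripted
    species-comparison, parameter-morphing, background-current,
    synaptic-depression-recovery and noise-robustness experiments, and a
    quadratic response-surface regression of accuracy on normalized membrane
    parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    yaml,
    jsonlite,
    lhs
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
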