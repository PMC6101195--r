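Package: stellate
Title: Conductance-Based Model Populations of Entorhinal Layer II Stellate Cells
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Single-compartment conductance-based modelling of medial entorhinal
    cortex layer II stellate cells. Provides Hodgkin-Huxley style kinetics for nine
    active conductances plus a six-state Markov SK channel and a cytosolic calcium
    pool, a fixed-step simulator with a compiled inner loop, the ten standard
    electrophysiological measurement protocols (resting potential and its stability,
    sag ratio, input resistance, impedance amplitude/phase and resonance, perithreshold
    membrane potential oscillations, firing responses and spike amplitude),
    rejection-sampling generation of heterogeneous valid-model populations with
    physiological validation bounds, virtual single-channel knockouts, population
    analytics (parameter and measurement correlations, normalized Euclidean and
    Mahalanobis distances, cross-set nonparametric comparisons), and
    spike-triggered-average characterization of spike initiation dynamics under
    Gaussian white noise.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
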