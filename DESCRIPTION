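Package: spindleloop
Title: Rate-Based Thalamocortical Circuit Simulation of Sleep Spindles
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates primate-style thalamocortical (TC) circuits with
    distinct core (parvalbumin-positive) and matrix (calbindin-positive)
    loops, a hybrid open/closed reticulo-thalamic loop design based on
    Gaussian connectivity kernels, local thalamic inhibitory interneurons,
    and variable-density layer 5 projections to the thalamic reticular
    nucleus (TRN). Neurons are single-compartment shunting (on-center,
    off-surround) rate units integrated on a one-dimensional array.
    Includes the measurement layer used to characterise simulated sleep
    spindles: the spindle tendency index (STI), sigma-band (5-15 Hz)
    band-pass checks, spatiotemporal activity maps, cosine-similarity
    angles between conditions, propagation latencies and spatial spread,
    plus named experiment presets and a calibration routine for the
    unconstrained synaptic gains.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'analysis.R'
    'kernels.R'
    'circuit.R'
    'config-io.R'
    'stimuli.R'
    'dynamics.R'
    'fixtures.R'
    'presets.R'
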