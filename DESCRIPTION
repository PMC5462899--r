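Package: synkin
Title: Synaptic Receptor Kinetics, Cleft Simulation and Single-Particle
    Tracking Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying fast inhibitory synaptic transmission at
    GABAergic synapses. Provides Markov models of GABA-A receptor gating
    with a deterministic master-equation solver and stochastic channel
    simulators; a particle-based Monte Carlo simulation of vesicular
    neurotransmitter release, diffusion in the synaptic cleft and
    activation of clustered postsynaptic receptors; analysis of inhibitory
    postsynaptic currents (sliding-template event detection, rise and
    decay kinetics, temperature coefficients); mean-squared-displacement
    analysis of single-particle tracking trajectories including confined
    diffusion fits and synaptic classification against presynaptic masks;
    and seed-deterministic synthetic-data generators with ground truth
    for every analysis stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
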