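Package: rdmecell
Title: Stochastic Reaction-Diffusion Simulation of Chemoattractant
    Signaling in Amoeboid Cells
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Spatial stochastic simulation of the chemoattractant signaling
    network that drives excitable behavior in amoeboid cells such as
    Dictyostelium discoideum. Discretizes a hemispherical membrane/cortex
    shell into an unstructured tetrahedral mesh and samples the
    reaction-diffusion master equation exactly with the Next Sub-volume
    Method (compiled event loop with per-voxel Gillespie direct channel
    selection). Ships modular reaction networks for multi-state G-protein
    coupled receptor kinetics, local excitation-global inhibition (LEGI)
    adaptation in difference, ratio and antithetic integral feedback
    variants, and a Ras/PIP2/PKB signal transduction excitable network,
    together with stimulus protocols (steps, staircases, pulses,
    micropipette gradients), a mean-field ODE oracle, and analysis tools
    for noise statistics, adaptation metrics, kymographs and wave events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
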