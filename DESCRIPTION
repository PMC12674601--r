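Package: ca3dyn
Title: CA3 Microcircuit Simulation and Local Field Potential Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Conductance-based simulation of a hippocampal CA3 microcircuit
    (O-LM, basket and multicompartment pyramidal cells with transient and
    persistent sodium currents) together with the analytics used to
    characterise its local field potential and spiking output:
    theta-gamma phase-amplitude modulograms and a monophasicity statistic,
    a noise-robust 0-1 test for chaos, stochastic largest Lyapunov
    exponents from perturbed twin simulations, epileptiform event and
    oscillatory burst detection, calcium-raster synchrony, and a
    genetic-algorithm procedure that fits circuit parameters to
    electrophysiological feature targets. Includes synthetic-signal
    generators with known ground truth for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
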