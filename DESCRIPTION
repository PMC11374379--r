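Package: crowdhop
Title: Docking-Based Minima-Hopping Simulation of Protein Diffusion in
    Crowded Solutions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates translational and rotational diffusion of proteins in
    crowded solutions by minima hopping on pre-computed rigid-body docking
    landscapes. Binary protein pairs are docked with a grid-based FFT
    correlation score; a Markov chain Monte Carlo engine with a
    detailed-balance-normalized Metropolis rule moves proteins between
    docked minima on neighboring molecules under periodic boundary
    conditions. The analysis stack computes mean-square-displacement
    translational diffusion coefficients, rotational autocorrelation
    tumbling times, Cohen-Turnbull concentration-slowdown fits,
    molecular-weight scaling fits, and homo- versus hetero-crowding
    comparisons, with synthetic generators (blob proteins, ideal Brownian
    trajectories, toy landscapes) providing exact oracles for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    igraph,
    minpack.lm,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
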