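Package: moranpg
Title: Spatial Moran Dynamics with Diffusible Public Goods
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic simulation of producer/nonproducer competition on a
    fully occupied periodic square lattice, where cooperation is mediated by a
    diffusible shared resource. Couples a spatial Moran (birth-death
    replacement) process with exact Doob-Gillespie event timing to the exact
    steady state of a screened-diffusion resource field, recomputed after
    every replacement. Includes neutral and mutualism control models, a
    saturating-uptake (Michaelis-Menten) variant, measurement tools
    (selection bias, radial distribution functions, fixation statistics,
    exponential decay-length fits) and scripted experiments for phase
    diagrams, critical-benefit searches and system-size scaling.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
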