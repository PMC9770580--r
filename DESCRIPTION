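Package: pmfperm
Title: Umbrella-Sampling Analysis of Membrane Permeability for Probe-Based
    PAINS Screening
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Plans umbrella-sampling window schemes along a lipid-bilayer
    normal, combines biased window time series into potentials of mean force
    by the weighted-histogram analysis method (WHAM), estimates
    position-dependent diffusion coefficients from per-window position
    autocorrelation, and integrates both into membrane permeability
    coefficients and entry/exit free-energy barriers under the inhomogeneous
    solubility-diffusion model (ISDM). Includes monolayer-referenced reaction
    coordinates and local membrane thickness from phosphate-atom coordinates,
    jackknife replicate errors, readers and writers for pull-output xvg time
    series, and an overdamped Langevin generator of synthetic umbrella data
    on known free-energy and diffusion landscapes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
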