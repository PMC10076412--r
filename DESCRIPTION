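Package: scmpop
Title: Spatial Cumulant Models for Interacting Cell Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and deterministic approximation of spatio-temporal
    point processes describing growth-factor-mediated cancer cell populations.
    Provides an exact Gillespie simulator for birth, facilitated birth, death
    and movement of marked points on a periodic plane; FFT-based estimators of
    first- and second-order spatial cumulants (densities and spatial
    covariances) from marked point patterns; numerical solvers for the closed
    mean-field and spatial-cumulant equation systems of the two-type
    growth-factor model, formulated in Hankel-transform space; and analytic
    derivation of spatially informed treatment doses (death rates) that zero
    the population growth at a chosen treatment time.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
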