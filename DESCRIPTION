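Package: notchwnt
Title: Notch-Wnt Crosstalk Simulation for Coupled Intestinal Crypt Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates a twelve-species ordinary differential equation
    model of Notch and Wnt signalling in intestinal crypt cells, with
    juxtacrine Delta-Notch coupling on a cell-contact graph and a Hes1
    promoter that integrates the two pathways.  Provides deterministic
    stiff integration with timed mutation events (APC knockout, Wnt
    hyperstimulation), a stochastic Hes1-noise extension, steady-state and
    linear-stability analysis, oscillation-period measurement and regime
    sweeps, a structural reaction-network representation with
    conservativity and weak-reversibility checks plus a numerical
    multistability probe, and sensitivity-ranked sequential parameter
    fitting with a synthetic-timecourse generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    boot,
    deSolve,
    igraph,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
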