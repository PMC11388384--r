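Package: topolimit
Title: Topology-Limited Morphogen Diffusion and Single-Particle Tracking Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based lattice simulation of morphogen diffusion with
    membrane-confined and free populations, under classic hindered-diffusion and
    topology-limited rules, with effective-diffusion (MSD slope) and
    effective-flux protocols and transition-rate sweeps across monolayer and
    bilayer tissue topologies. Companion single-particle-tracking toolkit:
    synthetic Markov-switching Brownian track generation with localization
    error, windowed maximum-likelihood diffusion spectra on a diffusion grid
    with error marginalization, K-state displacement hidden Markov model
    fitting with state lifetimes and jackknife intervals, transition-catalysis
    trend tests, bleach-trace normalization, and radial gradient
    quantification with exponential amplitude and lengthscale fits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    yaml,
    jsonlite,
    minpack.lm,
    rlang
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
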