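Package: capjet
Title: Reduced Modelling and Diagnostics for a Helium Cold Atmospheric-Pressure Plasma Jet
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying a dielectric-barrier-discharge helium plasma
    jet used to treat recombinant Pichia pastoris cultures. Provides the
    14-reaction helium chemistry with rate-coefficient evaluation and
    species/energy source terms; a steady laminar incompressible flow model
    of the jet channel; a reduced one-dimensional drift-diffusion-Poisson
    discharge model with dielectric surface charging under sinusoidal-AC or
    pulsed-DC drive; line-ratio optical-emission-spectroscopy estimators of
    electron temperature (Boltzmann pair He I 728.1/706.5 nm) and electron
    density (Saha-Boltzmann pair N2 357.6 nm / N2+ 391.1 nm); bioassay
    quantification (standard curves, Bradford/DNS/MTT/OD600 group
    statistics, densitometry) yielding percent-increase and fold-change
    summaries; and seeded synthetic-data generators for spectra, assay
    tables and discharge fixtures so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
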