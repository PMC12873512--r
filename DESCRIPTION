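Package: cuticular
Title: Leaf Cuticle Water Permeability, Microclimate and Raman Chemometrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying phenotypic plasticity of the leaf cuticle along
    alpine microclimate gradients. Simulates effective solar irradiance on
    tilted canopy surfaces from horizontally measured photon flux, estimates
    leaf minimum diffusive conductance (g_min) from bench-drying mass-loss
    curves (mass loss of detached leaves technique), fits an exponential
    temperature response of g_min, preprocesses and unmixes confocal Raman
    hyperspectral cubes of cuticle cross-sections (band-integration imaging,
    non-negative spectral unmixing, layer thickness measurement, band
    assignment), and runs the associated group-comparison statistics. A
    synthetic-data module generates microclimate series, drying curves,
    layered Raman cubes and thickness datasets with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    lubridate,
    Matrix,
    methods,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
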