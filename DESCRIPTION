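Package: beechoice
Title: Floral Trait Preference Analysis for Wild Bees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing floral trait preferences of bees from
    two-choice assays and supporting sensory measurements. Implements the
    hexagon colour-vision model for trichromatic bees (quantum catch with
    von Kries adaptation to the background, receptor excitation, hexagon
    loci, centre distances and colour angles) applied to reflectance
    spectra; binomial logistic preference models with a closed-form
    intercept oracle and integer inversion of published coefficient and
    standard-error pairs back to choice counts; scoring of
    electroantennographic (GC-EAD) response tables with an at-least-50
    percent activity rule; scent-mixture composition arithmetic;
    consumption-rate analysis for artificial flowers of different depths;
    and a seeded synthetic-data generator so every stage of the pipeline
    runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    broom,
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
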