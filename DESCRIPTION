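Package: triheme
Title: Microstate Thermodynamics of Triheme Cytochromes with a Redox-Bohr
    Center
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact 16-microstate thermodynamic model for triheme c-type
    cytochromes carrying one protonatable redox-Bohr center, as used to
    characterize the periplasmic cytochromes PpcA and PpcB of Geotalea
    uraniireducens and Geobacter sulfurreducens. Provides Boltzmann
    ensembles over oxidation x protonation microstates, derived redox
    observables (heme oxidation curves, stage-conditional oxidation
    fractions, macroscopic stage pKa values, midpoint and deprotonated-form
    potentials, dominant microstate routes), forward models for
    stage-resolved heme-methyl NMR chemical shifts and potentiometric
    visible redox titrations, simultaneous weighted least-squares
    estimation of the ten thermodynamic parameters from combined NMR and
    visible data, and a seeded synthetic-data generator for parameter
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    patchwork,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
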