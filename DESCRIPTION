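Package: pathtrap
Title: Kinetic Trapping and Synthetic Lethality in Reversible Molecular Pathways
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models a non-essential molecular pathway (such as recombinational
    DNA repair) as a three-state linear kinetic system with reversible steps, a
    potentially toxic intermediate and a compensatory route. Computes exact time
    courses and long-time state distributions, classifies genotype fates
    (repaired, compensated, death by damage, death by toxic trapping), simulates
    knockout and overexpression scenarios including within-reversible-pathway
    synthetic lethality and synthetic dosage lethality, sweeps phase diagrams
    over rate-ratio control parameters, and implements a normalized
    within-pathway negative genetic-interaction enrichment statistic with a
    seeded synthetic interaction-screen generator for validating it.
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
    jsonlite,
    Matrix,
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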