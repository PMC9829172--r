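Package: boombust
Title: Strain Coexistence in Boom-and-Bust Serial-Dilution Environments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Consumer-resource modelling of microbial strain coexistence under
    serial-dilution (boom-and-bust) protocols. Integrates within-cycle Monod
    growth dynamics for one or several co-utilized resources, runs
    growth-dilution cycles to steady state, evaluates closed-form pairwise
    coexistence criteria (leftover resource, total material, invasion
    fitness), solves an exactly tractable step-growth model with its
    closed-form n-strain coexistence probability, and assembles stochastic
    strain-pool ensembles that summarise survivor-count statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
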