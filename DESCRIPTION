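Package: trapdisp
Title: Dispersion Statistics, Sampling Plans and Experimental Design for
    Insect Trap Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying the spatial dispersion of insect
    populations from trap counts and for designing field-efficacy
    experiments on aggregated populations. Computes Lloyd's mean crowding,
    the index of dispersion with its chi-square randomness test, and Iwao
    patchiness regressions of mean crowding on mean density; derives
    enumerative sample-size curves and labor-cost estimates for fixed-
    precision sampling plans; estimates replication requirements for
    detecting proportional treatment reductions with one-sided t-tests on
    log-transformed counts; and compares completely random versus blocked
    (matched-pair) experimental designs by Monte-Carlo simulation of
    negative-binomial count experiments. A seeded synthetic trap-count
    generator with negative-binomial aggregation, seasonal decline and
    autocorrelated latent trap effects supports testing every stage
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    jsonlite
Suggests:
    glmmTMB,
    yaml,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
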