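Package: secflux
Title: Kinetic Modeling and Stable-Isotope Pulse-Chase Estimation of
    Recombinant Protein Secretion Fluxes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Structured first-order kinetic model of intra- and
    extracellular recombinant protein pools in chemostat culture, together
    with the full analysis chain for continuous stable-isotope (34S)
    pulse-chase labeling experiments: background correction and log-linear
    regression of 32S decay curves, steady-state estimation of the
    secretion, degradation and dilution time constants, partitioning of
    the intracellular formation rate into secreted, degraded and inherited
    fluxes, pairwise parameter-sweep sensitivity analysis of the secreted
    titer with an optional secretion-capacity cap, and a synthetic-data
    generator that emulates the labeling experiment with known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
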