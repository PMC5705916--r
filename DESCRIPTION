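Package: syntrophr
Title: Kinetic Simulation of a Fermenter-Diazotroph Cross-Feeding Mutualism
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Consumer-resource ordinary differential equation model of an
    obligate anaerobic mutualism between a fermentative Escherichia coli and
    a phototrophic, nitrogen-fixing Rhodopseudomonas palustris. E. coli
    ferments glucose into organic acids that feed R. palustris; R. palustris
    fixes N2 and excretes ammonium that feeds E. coli, while both species
    compete for the extracellular ammonium pool. Provides Monod-kinetic
    right-hand sides for two model variants (partial privatization of
    intracellularly generated ammonium, and a communal-pool control),
    adaptive batch integration, serial-transfer and pulsed fed-batch
    drivers, parameter scans over ammonium affinity ratios, excretion
    levels and inoculum ratios, outcome classification, critical-ratio
    bisection, and a command-line interface writing CSV results with JSON
    sidecars.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
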