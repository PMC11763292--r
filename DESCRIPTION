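Package: fishweb
Title: Trophic Indices, Mass-Balance Food Webs and Keystone Analysis for
    Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for ecosystem-level analysis of multi-species fisheries:
    trophic-level reconstruction of landings (mean trophic level, the
    Fishing-in-Balance index, and a region-based decomposition of the mean
    trophic level under fleet expansion), diet-composition handling and
    trophic-level computation, empirical life-history estimators (Pauly
    natural mortality, Hoenig longevity-based total mortality,
    Palomares-Pauly consumption rate), an Ecopath-style static mass-balance
    solver with derived ecosystem attributes including the primary
    production required to sustain catches, mixed trophic impact
    propagation, and impact/biomass keystone-group classification.
    Includes seeded synthetic-data generators for catch series and balanced
    food webs, packaged parameter tables for a sardine purse-seine
    ecosystem, CSV readers and writers, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
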