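Package: drylandsim
Title: Ecosystem Water Balance Simulation and Ecological Drought Analysis
    for Temperate Drylands
Version: 0.1.0
Authors@R:
    person("Dryland", "Modelling Group", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A daily, multi-layer, process-based ecosystem water-balance
    simulator for dryland cells, together with the climatological machinery
    needed to study how temperate drylands respond to climate change:
    Trewartha/aridity-index dryland classification, hybrid-delta construction
    of future daily forcing from monthly GCM change signals, ecological
    drought metrics based on soil-water-potential run lengths, and summary
    statistics (two-step GCM medians, unique-variance partitioning, Budyko
    curve fitting via Fuh's equation, and a symmetric agreement index).
    Includes a seeded synthetic-data module so the whole pipeline is testable
    at desk scale without external climate or soil archives.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
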