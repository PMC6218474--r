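Package: footprintr
Title: Cumulative Human Footprint Mapping and Extinction Risk Transition Modelling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a cumulative human-footprint (HFP) index from eight
    standardized pressure layers at two time points, classifies IUCN Red List
    category histories into low-risk and high-risk extinction-risk transitions,
    and quantifies how the extent and change of high-HFP area within species
    ranges predicts those transitions via threshold sweeps (Cohen's d,
    rank-sum tests) and a cross-validated random-forest classifier with
    permutation and Gini variable importance. Includes a seeded synthetic
    landscape and species generator with a planted threshold effect, per-realm
    analyses, and a reproducible pipeline over plain-text raster (Esri ASCII),
    GeoJSON, CSV and JSON formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
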