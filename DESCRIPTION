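Package: flaps
Title: Farm Location and Agricultural Production Simulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Spatial microsimulation of individual livestock farms from
    aggregate agricultural-census data. Imputes redacted population totals
    in hierarchical national/state/county census tables with customized
    iterative proportional fitting that honours published cells and
    farm-count bin bounds; fits and model-averages logistic farm-occurrence
    distribution models with AIC-based all-subsets selection; disaggregates
    binned county population totals into individual farms with a bounded
    one-dimensional raking step; and places farms on a 100 m occurrence
    probability surface with exclusion neighborhoods. Ships synthetic-data
    generators with known ground truth and reaggregation/substitution
    verification analyses based on absolute percent differences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
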