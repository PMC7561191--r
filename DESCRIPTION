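Package: seedalloc
Title: Stochastic Seeding Demand-Allocation of Land-Use Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downscales county-level land-use transition quotas into
    fine-grain categorical raster realizations with a tunable hybrid
    seeding algorithm that spans the continuum from random to contagious
    allocation. Includes negative-binomial patch-size modelling,
    random-forest transition-probability surfaces, multi-scale focal
    forest-fragmentation classification, ensemble coverage assessment,
    multi-decade trajectory projection, and a synthetic-landscape
    generator for fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    randomForest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
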