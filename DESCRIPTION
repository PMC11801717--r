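Package: VegRestore
Title: Vegetation Restoration Effectiveness Assessment and Geodetector
    Attribution
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to quantify the effectiveness of large-scale vegetation
    restoration from annual raster time series and to attribute it to
    environmental and management drivers. Builds fractional vegetation
    cover from NDVI with the dimidiate pixel model, combines normalized
    cover and net primary productivity into a composite quality-quantity
    index, grades per-pixel trends by least-squares slope and F-test
    significance, aggregates graded areas to county-level
    baseline-normalized effectiveness scores, and measures the explanatory
    power of stratified driver factors with the Geodetector q statistic,
    including significance, interaction and risk detection. A fully
    seeded synthetic-scenario generator with known ground truth (injected
    trends, change-point year, designed q values, designed land-use
    transition intensities) supports end-to-end validation without
    external data products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    knitr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
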