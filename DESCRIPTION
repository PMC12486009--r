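Package: trapfair
Title: Fairness Audit of Area-Level Traffic Pollution Exposure Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Compares three area-level aggregations of traffic-related air
    pollution exposure -- an EJ-Screen-style inverse-distance proximity at
    the areal-unit centroid, an AADT (annual average daily traffic) road
    density, and a parcel-based truck-traffic proximity reference -- across
    nested census-style geographies (block group, tract, ZCTA), and audits
    the fairness of each aggregation by testing whether its decile-scale
    errors relative to the parcel reference are associated with racial
    composition and material deprivation.  Includes a seeded synthetic
    county generator with nested areal units, heavy-tailed road traffic,
    clustered residential parcels, and a controllable copula linking
    demographics to road density, so the whole pipeline is testable
    without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
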