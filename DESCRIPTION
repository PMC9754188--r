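Package: parkactivity
Title: Green-Space Human Activity Metrics from Anonymized Mobility Tiles
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to estimate human activity in managed green spaces from
    anonymized, gridded smart-device activity tiles. Provides a forward
    simulator of the anonymization pipeline (thresholding, additive noise,
    baseline normalization) over synthetic landscapes, geometry utilities for
    clipping activity cells to property polygons, an overnight-activity
    exclusion filter for road contamination, per-property activity density and
    coverage metrics, trail and land-cover attribution, reservation-based
    validation models, and a partial canonical correspondence analysis with
    permutation testing for relating activity to tree community composition.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
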