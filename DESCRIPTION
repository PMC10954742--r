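Package: nismomentum
Title: Momentum-Based Spatio-Temporal Analysis of Non-Indigenous Species Spread
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decodes the spread of non-indigenous species (NIS) from historical
    first-detection records. Converts dated, region-tagged sightings into
    per-species momentum sequences (ordered first records per country), derives
    delta-of-momenta year-gap distributions and their empirical-CDF medians,
    builds cumulative median spread curves under an all-records and a
    dominant-hotspot scenario, selects dominant hotspot country sets per
    momentum, constructs buffered-polygon centroids and the entry-point-anchored
    spread trajectory, and validates inferred spread durations against
    georeferenced invasion histories of individual species. Includes a seeded
    synthetic spread-data generator and an end-to-end pipeline with a
    reproducible run manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    geosphere,
    jsonlite,
    polyclip,
    stats,
    tools,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
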