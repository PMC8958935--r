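Package: trawlwatch
Title: Fisher Self-Reported Trawl Tracks, Discards and Map Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing fisher self-reported data in small-scale
    bottom-trawl fisheries: a synthetic fleet simulator with ground-truth
    trawling labels, a GPS track cleaning cascade (study-area, land-buffer,
    speed, gap and endpoint-buffer filters with 3-minute regularization),
    random-forest inference of trawling activity from step distance, turning
    angle and time of day, per-trip discard proportions and observer/fisher
    weight calibration, 500 m effort and discard rasters, and a
    similarity-in-means index for comparing fisher- and observer-derived
    usage maps over 3x3 neighbourhoods.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    geosphere,
    randomForest,
    stats,
    utils,
    xml2
Suggests: testthat (>= 3.0.0), jsonlite, withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
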