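Package: thinhorn
Title: Migration Strategy Classification for GPS-Collared Mountain Ungulates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for classifying the seasonal movement
    strategies of GPS-collared mountain ungulates such as Stone's sheep.
    Reads and cleans raw collar fixes, computes net squared displacement and
    detects the timing of spring and fall geographic migrations, estimates
    seasonal ranges and migration corridors with a from-first-principles
    Brownian bridge movement model on a 50 m grid, delineates stopover
    sites, extracts elevation use from a digital elevation model, and fuses
    the results into a six-way migration-strategy label (long-distance,
    short-distance and vacillating geographic migrants; traditional and
    abbreviated altitudinal migrants; residents). Includes a seeded
    ground-truthed track simulator so every stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    geosphere,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
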