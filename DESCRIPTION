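Package: floodaccess
Title: Healthcare Accessibility and Road Criticality Under Flood Disruption
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares network-based (road graph shortest paths) and
    raster-based (least-cost paths over a friction surface) estimates of
    travel time to the nearest health facility, before and after a flood
    event. Floods are applied by removing road-network nodes inside the
    flood mask and by forbidding travel through flooded raster cells.
    Population counts are attributed to travel-time bins to quantify the
    loss of accessibility, and a targeted edge betweenness centrality
    indicator scores road-segment criticality for healthcare access,
    identifying both flood-critical segments and backup roads. A seeded
    synthetic-scenario generator (classed road network, clustered
    population, friction surface, ribbon flood) makes the whole pipeline
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
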