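Package: dynexposure
Title: Dynamic PM2.5 Exposure Assessment Along GPS Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rapid assessment of dynamic fine-particulate (PM2.5) exposure for
    vehicle-based workers such as taxi drivers. Fuses an annual pollution
    raster with hourly monitoring-station series into a spatio-temporal
    concentration field, map-matches raw GPS trajectories to a road network
    with a hidden Markov model, integrates exposure along occupied trips,
    and summarises exposure by hour, day and driver subgroup with
    air-quality-guideline comparisons and kernel-density activity hotspots.
    Includes a fully deterministic synthetic scenario generator (annual
    raster, station series with diurnal cycle and pollution episode, road
    lattice, noisy taxi trajectories with ground truth) for validation.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    geosphere,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
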