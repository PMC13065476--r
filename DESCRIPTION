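Package: musselsmce
Title: Spatial Multi-Criteria Evaluation for Offshore Blue-Mussel Site Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial multi-criteria evaluation (SMCE) pipeline for siting
    offshore blue-mussel (Mytilus edulis) longline aquaculture and ranking
    co-location options with offshore wind farms. Combines a Boolean
    feasibility stage (heat-spike run detection in daily sea-surface
    temperature, bathymetry band, current-speed limit) with a fuzzy-logic
    suitability stage (physiological membership functions for temperature,
    chlorophyll a, salinity and suspended sediment; analytic hierarchy
    process weights with Saaty consistency checking; weighted raster
    overlay and five-class mapping), auxiliary accessibility criteria
    (wave-height operability, distance to port), climate-scenario
    suitability change from decadal-mean temperature projections, and
    zonal-statistics ranking of wind-farm polygons. Ships a seeded
    synthetic ocean-scenario generator so the full pipeline runs and is
    testable without any external data download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    geosphere,
    jsonlite,
    mgcv,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
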