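Package: accesscape
Title: Raster-Based Geographic Accessibility and Coverage Modelling for
    Health Facilities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring geographic accessibility of health
    services on raster landscapes: anisotropic least-cost travel time
    toward facilities under multimodal travel scenarios (with the Tobler
    hiking correction for walking), Euclidean-buffer proximity analysis,
    capacity-constrained catchment delineation with served/unserved
    population accounting, zonal (medical-block) coverage statistics, and
    a conflict-scenario remodelling of walking access. Ships a seeded
    synthetic-landscape generator (elevation, land cover, tiered roads,
    river barriers, gridded population, facilities, villages) so the full
    pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
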