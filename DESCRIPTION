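Package: msfd9
Title: Environmental Quality Assessment of Seafood Contaminants Under
    MSFD Descriptor 9
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for assessing Good Environmental Status of marine
    waters under Descriptor 9 of the Marine Strategy Framework Directive
    (2008/56/EC), which requires that contaminants in fish and other
    seafood for human consumption do not exceed regulatory levels.
    Implements the statistical range of acceptance (a lognormal model
    anchored at the geometric mean with 20 percent dispersion, the
    regulatory level placed at its 90th percentile, compliance judged by
    the empirical 90th percentile), a regulatory catalog of foodstuff
    category limits, record-level quality-control filtering, a fishnet
    grid in ETRS89 geographic coordinates with station-to-cell
    integration under majority and precautionary-tie rules, summary
    statistics (spatial coverage, exceedance frequencies, percentages
    within limits at data, station and cell level), green/red cell map
    export as GeoJSON, and a seeded synthetic-data generator emulating
    per-category lognormal concentrations at spatially scattered
    stations with controllable exceedance fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
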