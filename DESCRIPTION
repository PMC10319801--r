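Package: plasticrisk
Title: Marine Plastic Exposure Risk Mapping from Seabird Tracking Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for estimating relative marine plastic
    exposure risk of wide-ranging seabirds from multi-device tracking data
    (GPS, PTT, GLS) and gridded ocean plastic-density model outputs.
    Implements track standardisation and quality filtering, breeding
    phenology classification from distance to colony, monthly kernel
    utilisation distributions on an equal-area grid, geometric-mean fusion
    of plastic-density model layers with missing-data fallback, spatial
    overlap scoring of bird density against plastic density, and
    attribution of exposure to Exclusive Economic Zones, joint maritime
    regimes and the high seas. Includes a seeded synthetic-data generator
    that emulates the statistical structure of restricted-access tracking
    datasets so the whole pipeline is testable and reproducible.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    geosphere,
    mgcv,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
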