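Package: carbonscape
Title: LiDAR-Assisted Mapping of Aboveground Forest Carbon at Hectare Resolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for estimating and mapping aboveground carbon density (ACD)
    from field inventory plots, airborne LiDAR canopy height, and satellite
    covariates. Implements plot-level allometric carbon estimation with
    wood-density fallbacks and height-diameter models, maximum-likelihood
    calibration of a heteroskedastic power law linking top-of-canopy height to
    carbon density, satellite covariate engineering (compositing, cross-sensor
    backfill, terrain derivatives, climate smoothing), landscape upscaling by
    covariate stratification and random-forest regression, and per-pixel
    uncertainty propagation with ecoregion bias validation. Includes a
    synthetic-landscape simulator with known generating parameters so the full
    pipeline can be exercised and validated end to end.
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
    jsonlite,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
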