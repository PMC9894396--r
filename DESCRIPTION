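Package: droughtsens
Title: Crop Yield Sensitivity to Drought from Gridded Precipitation and Yields
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying how strongly crop
    yields respond to meteorological drought on a regular latitude-longitude
    grid. Monthly precipitation is accumulated and standardized into the
    Standardized Precipitation Index (SPI) via per-calendar-month gamma
    fits, projected onto each grid cell's harvest month to form an annual
    drought index, and regressed against percent yield anomalies around a
    local-polynomial yield trend to give a per-cell drought sensitivity
    (slope, percent yield change per unit drought magnitude). Downstream
    tools summarize significance and sign across cropland, split cells into
    irrigated and rainfed classes, histogram harvested area by sensitivity
    bin, and attribute the spatial pattern of sensitivity to physical and
    socioeconomic determinant rasters with a random-forest regressor
    (out-of-bag skill, impurity importance, partial dependence). A
    synthetic-data module generates every input with known ground truth so
    each stage has a recovery test.
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
    ncdf4,
    pracma,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
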