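Package: popdasym
Title: Multi-Temporal Dasymetric Population Mapping with Random Forests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Top-down disaggregation of census population counts onto a grid
    using random-forest dasymetric weighting. Builds per-year covariate stacks
    (temporally interpolated built-up fraction, land-cover class and
    distance-to layers, distances to roads and rivers, terrain), fits
    regression forests on log population density of administrative units,
    predicts pixel-level weighting surfaces, redistributes counts
    mass-conservingly with exclusion masks, and compares a single-year
    transferred model (M1) against year-specific models (M2) by
    reaggregation against finer census data. Includes a seeded synthetic
    landscape generator with nested admin hierarchies and known ground truth
    so the whole pipeline is testable without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    ranger,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    randomForest,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
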