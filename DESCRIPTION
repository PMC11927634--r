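Package: lakedo
Title: Reconstruction, Attribution and Projection of Lake Surface Dissolved Oxygen
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing surface dissolved oxygen (DO) in lakes from
    climate forcing, satellite water-colour features and geographic attributes, and
    for analysing the result. Implements the floating algae index and CIE
    chromaticity hue angle from multispectral water-leaving reflectance, oxygen
    solubility (Benson-Krause with pressure correction) and saturation-departure
    decomposition, matchup construction under strict time windows, a random-forest
    DO retrieval model with feature scaling and grid search, Theil-Sen /
    Mann-Kendall trend analysis on hemisphere-aware summer medians, day-specific
    percentile-climatology heatwave detection with counterfactual impact
    quantification, standardized path-coefficient attribution of DO change to
    solubility and eutrophication, low-oxygen stress metrics, and scenario-driven
    DO projection with ensemble spread. A fully seeded synthetic-lake generator
    emulates the statistical structure of the real inputs so the entire pipeline is
    testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    lubridate,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    ranger,
    xgboost,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
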