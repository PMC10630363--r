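Package: empsuit
Title: Empirical Habitat-Suitability Modelling from Out-Plant Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for estimating climatic habitat suitability of a
    species from experimental out-planting trials rather than occurrence
    records. Processes raw climate-station logs into gap-filled daily
    series and period climate summaries, computes site-level survival and
    growth metrics from out-plant monitoring records, enumerates and ranks
    candidate climate models by AICc with collinearity screening, projects
    the chosen survival model over gridded climate fields with station-based
    bias correction to produce bounded suitability indices, historical trend
    maps and future extrapolations, and provides a simplified occurrence-based
    species distribution model for comparison. A synthetic-data generator
    with known ground truth makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    jsonlite,
    mgcv,
    glmnet,
    withr,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
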