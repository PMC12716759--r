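Package: dualniche
Title: Dual Climate-Soil Niche Modelling with Tree Ensembles, Exact
    Shapley Attribution and Niche Overlap
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An ecological niche modelling toolkit for host-parasite plant
    systems in arid landscapes. Builds separate climate and soil habitat
    suitability models from presence records and dual-filtered
    pseudo-absences (environmental profiling plus K-means eligibility),
    fits a four-member random forest / gradient boosted tree ensemble under
    repeated spatial block cross-validation, and integrates climate, soil
    and host suitability by the per-cell minimum ("barrel effect") rule.
    Includes exact subset-enumeration Shapley attribution for the fitted
    ensembles, Schoener's D niche overlap with categorical bands,
    latitude-weighted suitable-area accounting with scenario change
    summaries, and a synthetic-landscape generator with known truth
    suitability for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
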