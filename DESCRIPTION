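Package: pcosmet
Title: Predictors of Metformin Response in PCOS via Semantic Connectivity Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for identifying baseline predictors of
    metformin response in women with polycystic ovary syndrome (PCOS).
    Provides a longitudinal cohort data model with derived endocrine indices
    (free androgen index, HOMA-IR, BMI, waist/hip and LH/FSH ratios),
    outcome labelling and study-flow accounting; a seeded synthetic cohort
    generator with planted response and drop-out structure; median
    dichotomization into paired HIGH/LOW nodes; auto-contractive map
    (Auto-CM) associative networks with minimum-spanning-tree filtering into
    semantic connectivity maps; evolutionary feature selection with
    backpropagation neural-network fitness (TWIST-style) and ROC evaluation;
    and the classical inference stages (Friedman, Mann-Whitney, logistic
    regression with odds ratios, two-by-two risk tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
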