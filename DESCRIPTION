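Package: ffqreduce
Title: Shortening Food Frequency Questionnaires with Correlation Subsets
    and PROMETHEE Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimising non-quantitative food frequency
    questionnaires (FFQs). Computes nutrient intake amounts and discrete
    diet-quality scores from consumption-frequency answers, builds nested
    question subsets by Pearson-correlation thresholding, benchmarks
    machine-learning predictors against zero-imputation and
    chained-equations imputation baselines under shared cross-validation,
    and ranks methods and subsets with the PROMETHEE outranking scheme
    (V-shaped preference function, positive/negative/net preference
    flows, fractional ranks). Includes a Gaussian-copula generator for
    synthetic ordinal FFQ cohorts with planted correlation structure and
    deterministic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    withr,
    MASS,
    nnet,
    rpart,
    e1071,
    ipred,
    caret,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
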