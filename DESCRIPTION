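Package: foodscape
Title: State-Level Food-Environment Scoring and Obesity-Rate Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Characterizes regional food environments from business-listing
    and crowd-sourced nutrition data: per-state availability of food
    categories, affordability (price tier) and acceptability (ratings,
    reviews), caloric density of dishes and categories from gram-denominated
    nutrition records, and an availability-weighted caloric-density score per
    state. Provides two-proportion z-tests for between-state availability
    contrasts, leave-one-out cross-validated regression of state obesity
    rates on the derived feature sets (linear, random forest, support vector
    machine, gradient-boosted trees), and a synthetic-world generator with a
    planted environment-obesity link for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    MASS,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
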