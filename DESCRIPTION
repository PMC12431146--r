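Package: glucolens
Title: Postprandial Glucose Analytics from Wearables, Food Logs and Work Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A multimodal pipeline for predicting postprandial glycemic
    response from continuous glucose monitor (CGM) traces, thigh-worn
    activity event streams, food logs and work logs. Computes postprandial
    area under the glucose curve (AUC), incremental AUC, maximum
    postprandial glucose and hyperglycemia labels; engineers glycemic-load
    and activity-duration feature sets; trains random-forest, ridge,
    multilayer-perceptron and gradient-boosting backbones with Gaussian
    feature augmentation and ADASYN class balancing; fuses zero-shot
    language-model predictions into hybrid regressors; and explains
    hyperglycemia predictions with diverse counterfactual treatment
    pathways and Shapley-style feature attributions. Includes a synthetic
    cohort generator with known ground-truth effect structure for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    hms,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    withr,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
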