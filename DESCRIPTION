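Package: trophicstate
Title: Lake Trophic State Classification from Landsat Reflectance via the
    Nutrient-Color Paradigm
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies lake trophic state (oligotrophic, eutrophic/mixotrophic,
    dystrophic) from per-overpass satellite surface reflectance using the
    Nutrient-Color Paradigm: in situ total phosphorus and true color define
    reference states, per lake-year median summer reflectances are normalized
    to relative band fractions and z-scored, and a three-model ensemble
    (multinomial logistic regression, gradient boosted trees, multilayer
    perceptron) is fit under lake-level spatial cross-validation. Includes a
    synthetic-data generator with known ground truth, published-schema
    prediction writers, and a quality-control battery: confusion and balanced
    accuracy metrics, one-vs-rest ROC/AUC, exact Shapley feature attribution,
    Type II sum-of-squares ANOVA on lake properties, threshold-proximity
    misclassification profiles, and group-wise trophic-state proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    nnet,
    xgboost,
    car,
    yaml,
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
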