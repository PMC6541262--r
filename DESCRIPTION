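Package: cultshare
Title: Cross-Cultural Analysis of Food-Sharing Practices in Small-Scale Societies
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing whether the presence and dissimilarity of food-sharing
    practices across small-scale societies track socio-ecological conditions or
    geography. Implements binary trait encoding of 14 basic sharing practices,
    Hamming dissimilarity and great-circle distances, the unordered pairwise
    difference design, an assumption-routed two-sample test battery
    (t, Wilcoxon-Mann-Whitney, Fligner-Policello, Brunner-Munzel) with seven
    multiple-testing corrections, a from-scratch dependence screen (maximal
    information coefficient, distance correlation, and the Heller-Heller-Gorfine
    permutation test), a weighted shared-practice network, and a predictive null
    comparison of regression learners against the mean predictor via nested
    cross-validation and ANOVA. Includes a synthetic-data generator with null,
    covariate-effect, and geographic-diffusion regimes, and ships the published
    practice inventory of 22 societies as a built-in fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    igraph,
    car,
    rpart,
    randomForest,
    xgboost,
    e1071,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    withr
Config/testthat/edition: 3
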