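Package: elevtrait
Title: Functional Traits and Species Elevational Optima on Phylogenies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates species elevational optima from presence/absence
    records along an elevation gradient with the Huisman-Olff-Fresco (HOF)
    hierarchy of response models, and relates interspecific variation in
    those optima to functional traits with phylogenetic generalized least
    squares under maximum-likelihood Pagel's lambda. Provides a sequential,
    category-wise exhaustive-AIC model selection framework (morphology,
    then anatomy, then physiology) with delta-AIC-when-omitted predictor
    importance, single-predictor trait screens with Holm-Bonferroni
    family-wise error control, phylogenetic principal component analysis
    with passively projected growth-form centroids, and a synthetic-data
    generator (Yule trees, lambda-structured traits, unimodal occurrence
    curves) so every stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
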