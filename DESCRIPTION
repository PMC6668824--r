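Package: metamemnet
Title: Neural-Network Individual-Differences Analysis of Memory and
    Metacognition in Aging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying individual differences in recognition memory
    and metacognitive monitoring across younger and older adults. Implements
    a small bipolar-logistic multilayer perceptron trained by full-batch
    error-correction backpropagation to classify participants by age group
    from 18 memory and metacognition measures, probing of its hidden-unit
    activations, k-means clustering of the latent space with canonical
    cluster labelling, cluster-wise one-way ANOVAs with Bonferroni correction
    and partial eta squared, leave-one-out cross-validated d-prime with
    item-versus-associate feature ablation, the classical split-plot mixed
    ANOVA on recognition scores, pooled t tests and Cohen's d, and a
    synthetic-cohort generator with a latent three-cluster structure and
    ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
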