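Package: biovnn
Title: Pathway-Structured Visible Neural Networks for Cancer Dependency
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts gene-level cancer dependencies from RNA expression
    profiles with a visible neural network whose sparse architecture mirrors
    a curated pathway hierarchy. Each hidden neuron block corresponds to a
    pathway, connections follow gene-pathway and pathway-pathway membership,
    and per-pathway auxiliary classifiers provide deep supervision. Includes
    matched fully connected and randomized-pathway baselines, class- and
    tissue-balanced cross-validation, AUROC/AUPRC evaluation with cross-fold
    pooling, time-stamped (train-on-old, test-on-new) evaluation, and
    interpretability analyses: pathway neuron-state class separation,
    per-prediction pathway-state explanation, reaction-partner feature
    importance enrichment, and pathway recovery from dense-network weights.
    A synthetic-data generator with a planted pathway-dependent mechanism
    makes every analysis testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
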