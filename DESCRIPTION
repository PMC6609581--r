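Package: dbnexpr
Title: Deep Belief Network and Hybrid SVM Classifiers for Gene Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classification of high-dimensional gene-expression profiles with
    deep belief networks and hybrid deep-network/support-vector-machine
    classifiers. Provides binary-unit restricted Boltzmann machines trained by
    contrastive divergence, greedy layer-wise pretraining, supervised
    fine-tuning by backpropagation (SGD with momentum and weight decay) or
    resilient backpropagation (iRprop+ with weight backtracking), autoencoders
    unfolded from pretrained RBM stacks, and combined classifiers that feed a
    learned hidden-layer representation into an SVM. Includes an evaluation
    harness with class-balancing undersampling, stratified k-fold
    cross-validation, and confusion-matrix metrics (accuracy, sensitivity,
    specificity, error rate) with standard errors, plus a synthetic
    expression-data generator with known differential structure for testing
    every stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
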