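Package: connectomeBench
Title: Standardized Benchmarking and Interpretation of Classifiers on
    Multi-Site Connectome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A standardized framework for training, comparing and
    interpreting machine-learning classifiers on multi-site case/control
    neuroimaging feature tables. Provides a synthetic multi-site cohort
    generator with planted class effects, functional-connectivity and
    structural feature assembly with strictly train-only ridge
    recursive-feature-elimination, five classifier architectures (kernel
    SVM, fully connected network, autoencoder-classifier, Chebyshev
    graph convolutional network on a site population graph, and an
    edge-variational graph network with a trainable pairwise association
    encoder), leakage-free stratified cross-validation and nested
    cross-validation pipelines, majority-voting ensembles, and a
    SmoothGrad saliency signal-to-noise stability analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
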