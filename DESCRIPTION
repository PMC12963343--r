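Package: fllsnet
Title: Federated Image Classification with a Large-Small Kernel Network and
    Quality-Aware Aggregation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale federated learning simulation framework for image
    classification. Implements a lightweight convolutional backbone built on
    large-kernel perception and small-kernel dynamic aggregation (LS
    convolution), baseline federated optimizers (FedAvg, FedProx), and a
    quality-aware aggregation rule that weights clients by convergence
    velocity, training stability, and prediction-confidence reliability via a
    softmax over z-scored composite scores. Ships a synthetic foliar-lesion
    image generator with per-client sensor heterogeneity and Dirichlet
    label-skew partitioning, classification metrics, results-table analysis
    utilities, a linear convergence-bound checker for strongly convex
    objectives, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    ranger,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
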