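Package: mcsm
Title: Multi-View Clustering of Omics Samples on Stiefel Manifolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Joint clustering of samples measured on several omics platforms
    (multi-view clustering). Per-view patient similarity graphs are built with a
    heat-kernel affinity restricted to k nearest neighbours, combined into a
    block Laplacian with identity coupling blocks, and the relaxed spectral
    objective trace(U' L U) is minimised over a product of Stiefel manifolds by
    projected gradient descent with Armijo backtracking and an SVD (polar)
    retraction. Per-view k-means labellings of the embedding are aligned by
    Hungarian matching and integrated by a k-nearest-neighbour majority vote.
    Includes a multi-view stochastic-block-model simulator with view-specific
    cluster distributions, Rand index / normalised mutual information
    evaluation over replicate simulations, and a preprocessing chain for real
    omics matrices (missing-data filtering, KNN imputation, log transform,
    feature standardisation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
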