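Package: cardiodx
Title: Heart-Disease Risk Classification with K-Means Denoising, Kernel
    Discriminant Features and a Spectral Graph Convolutional Network
Version: 0.1.0
Authors@R:
    person("cardiodx", "maintainers", email = "cardiodx@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for binary heart-disease risk
    classification from tabular clinical records in the UCI heart-disease
    "processed" CSV dialect. Records are denoised by distance-quantile
    filtering on a K-means clustering, embedded by linear or kernel
    discriminant analysis with (alpha, gamma)-regularized class covariances
    and a Mahalanobis/Bayes decision rule, connected into a patient
    similarity k-nearest-neighbour graph, and classified transductively by
    a spectral graph convolutional network with polynomial Laplacian
    filters and a normalized-min-cut auxiliary loss. Includes a synthetic
    clinical-table generator, evaluation metrics (confusion counts, ROC
    AUC), epoch-wise reporting and a command-line interface.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
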