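Package: lromics
Title: Integrative Low-Rank Dimension Reduction and Clustering of Multi-Omics Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates heterogeneous feature-by-sample omics matrices
    (continuous, binary, count, and dummy-coded categorical data) into one
    shared low-dimensional subspace through a convex, nuclear-norm-regularized
    exponential-family likelihood model. The penalized likelihood is minimized
    by alternating gradient steps with singular-value shrinkage, the shrinkage
    level re-chosen each iteration as the (r+1)-th largest singular value so
    that the fitted parameter matrix has rank at most r. Samples are clustered
    in the reduced subspace with k-means, the number of clusters chosen by
    silhouette values and the rank by an explained-variation statistic.
    Includes a synthetic multi-omics generator with planted low-rank cluster
    structure, per-cluster signature tests, delimited-text input and output,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    cluster,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
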