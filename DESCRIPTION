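Package: lactoclust
Title: Shape-Based Clustering and Modelling of Dairy Lactation Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing daily milk-yield records from dairy herds:
    rule-based exclusion of incomplete lactations, gap interpolation,
    moving-average smoothing and Z-score normalization; k-medoids clustering
    of lactation-curve shapes under a root-mean-square Euclidean distance
    with squared-distance-weighted initialization and elbow-based selection
    of the cluster number; nonlinear least-squares fitting of the Wood,
    Wilmink and Dijkstra lactation-curve models to cluster-representative
    curves; closed-form peak-yield, peak-time and persistency features; fit
    error statistics and cluster comparison via one-way ANOVA with Fisher's
    LSD compact letters. Includes a synthetic herd generator with ground
    truth labels for validating every stage of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    lhs,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
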