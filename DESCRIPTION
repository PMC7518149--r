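Package: milkorder
Title: Unsupervised Analysis of Dairy Cow Milking-Order Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for exploratory analysis of parlor entry-order ("milking
    order") records from dairy herds. Converts raw ordinal entry logs to entry
    quantiles and applies standard record filters; quantifies queue-formation
    stochasticity with conditional Shannon entropies, per-cow variance, and
    within-day permutation nulls; visualizes inter-animal relationships with
    PCA and a graph-Laplacian (diffusion-map) embedding including a
    harmonic-artifact reference; exposes heterogeneous temporal
    non-stationarity and outlier days with Data Mechanics iterative
    co-clustering; and tests associations between queue-derived groupings,
    cow attributes, and accelerometer time budgets with mutual conditional
    entropy permutation tests. A synthetic herd generator reproduces the
    statistical structure these analyses assume, so the whole pipeline is
    testable without farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    pheatmap,
    optparse
Config/testthat/edition: 3
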