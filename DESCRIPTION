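Package: heartsvg
Title: Spatially Variable Gene Detection by Serial Autocorrelation of
    Marginal Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distribution-free identification of spatially variable genes
    (SVGs) in spatial transcriptomics count data. Gene expression on the
    tissue is semi-pooled into one-dimensional marginal expression series
    along the row and column axes at two resolutions; serial autocorrelation
    of each series is tested with a Portmanteau (Box-Pierce type) statistic,
    the four p-values are combined by Stouffer's method and adjusted across
    genes with Holm's procedure. Includes a labelled synthetic-data generator
    (Poisson-process spot placement, a 22-pattern catalog, Poisson/ZIP/NB/ZINB
    counts, three noise models), confusion-matrix and AUC benchmarking
    utilities, and an auto-clustering module that groups SVGs by spatial
    profile similarity, cuts the dendrogram with a breakpoint
    (Yamamoto-type) test, and predicts spatial domains per cluster.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite,
    optparse
Config/testthat/edition: 3
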