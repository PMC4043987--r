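Package: bipfs
Title: Minimum-Redundancy Feature Selection for Expression Data by a
    Relaxed Binary Integer Program
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Filter-style feature selection for labeled expression
    matrices (bulk or single-cell, samples by features). Features are
    ranked by the solution of a convex quadratic program that trades
    class separability -- a graph-Laplacian linear term over a +/-1
    class-agreement matrix -- against pairwise Pearson redundancy among
    the selected features. The correlation matrix is replaced by a
    Nystrom low-rank factorization anchored on k-means landmark
    pseudo-features, so the whole pipeline scales linearly in the number
    of features. A multi-task mode selects one shared feature subset
    across several related datasets. Includes GCT/CLS/TSV readers and
    writers, a synthetic-data generator with known informative,
    redundant-block and noise structure, a leakage-free holdout AUC
    harness, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    graphics,
    quadprog,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
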