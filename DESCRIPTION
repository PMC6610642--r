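Package: wgrmf
Title: Weighted Graph-Regularized Matrix Factorization for Drug Response Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts anticancer drug response in cell lines by weighted
    graph-regularized matrix factorization. Builds drug and cell-line
    similarity matrices (Jaccard on binary fingerprints, Pearson on
    expression profiles), sparsifies them through p-nearest-neighbor
    graphs, and factorizes the partially observed drug-by-cell-line
    response matrix under Tikhonov and normalized-graph-Laplacian
    regularization with alternating row-wise updates. Includes repeated
    k-fold cross-validation with per-drug metrics, hyperparameter grid
    search, case-study utilities (ranking unmeasured cell lines, rank-sum
    group comparison), a synthetic data generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
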