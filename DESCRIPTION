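Package: circpath
Title: Path-Weighted Prediction of circRNA-Disease Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts circRNA-disease associations by path-weighted scoring on a
    heterogeneous network. Annotation-based Jaccard similarities (GO terms for
    circRNAs, disease-gene annotations for diseases) are fused with Gaussian
    interaction profile (GIP) kernel similarities computed from the known
    association matrix; the fused similarity networks and the bipartite
    association network form a weighted heterogeneous graph, edges below a
    weight threshold are pruned, and each circRNA-disease pair is scored by
    summing the products of edge weights over all bounded-length simple paths
    connecting them, discounted exponentially by path length. Includes
    leave-one-out and k-fold cross-validation with per-fold network rebuilding,
    ROC/AUC evaluation, a seeded planted-block synthetic data generator, plain
    delimited-text readers and writers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    igraph,
    jsonlite
Config/testthat/edition: 3
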