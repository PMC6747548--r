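Package: divepred
Title: Multi-View Non-Negative Matrix Factorization for Drug-Disease
    Association Prediction
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Predicts drug-disease association scores for drug repositioning
    by jointly factorizing four drug feature views (chemical substructures,
    target protein domains, target gene-ontology annotations, and
    associated-disease profiles) under a diversity (orthogonality) penalty,
    masked reconstruction of known associations, dual graph-Laplacian
    smoothness over drug and disease k-nearest-neighbour graphs, and l1
    sparsity, optimized by multiplicative updates. Includes the per-drug
    cross-validation evaluation protocol (AUC, AUPR, recall at k), a seeded
    synthetic-data generator with planted low-rank structure, dense TSV and
    sparse Matrix Market I/O, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
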