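Package: lgdti
Title: Drug-Target Interaction Prediction from Local and Global Graph Representations
Version: 0.1.0
Authors@R: person("lgdti", "maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts drug-target interactions (DTIs) by representing each node
    of a bipartite drug-protein graph three ways: intrinsic attributes (Morgan
    fingerprint bits for drugs, 3-mer composition over a 4-group reduced
    amino-acid alphabet for proteins), local structure via a one-layer graph
    convolution with raw-attribute re-injection, and global structure via
    DeepWalk skip-gram embeddings trained on truncated random walks. Drug-protein
    pairs are classified (random forest by default) under stratified k-fold
    cross-validation, with a synthetic planted-partition benchmark generator
    and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
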