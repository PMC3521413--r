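Package: betopr
Title: Graph-Based Prediction of Conformational B-Cell Epitopes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts conformational B-cell epitopes on antigen surfaces with
    a graph model. An antigen surface is represented as a residue-level
    contact graph built by Delaunay tessellation of solvent-exposed atoms;
    edges are weighted by chi-squared and log-odds propensities of residue
    type pairs learned from antibody-antigen complexes; Markov Clustering
    partitions the weighted graph into subgraphs; and an ensemble of
    class-balanced support vector machines with trust-reliable voting
    classifies each subgraph as epitope or non-epitope. Includes training
    from antibody-antigen complex structures, prediction for unbound
    antigens, evaluation metrics (including epitope non-planarity and
    multi-epitope ground-truth construction), and a seeded synthetic-complex
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    bio3d,
    e1071,
    jsonlite,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
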