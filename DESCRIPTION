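Package: netalign
Title: Bayesian Pairwise Alignment of Biological Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Global pairwise alignment of bio-molecular networks (protein-protein
    interaction networks, gene co-expression networks) that scores both
    cross-network vertex similarity and edge (interaction) conservation with
    log-likelihood ratios. All scoring parameters are inferred from the data by
    an iterative maximum-likelihood scheme; high-scoring alignments are found by
    linearising the quadratic assignment objective and solving repeated linear
    assignment problems with annealing noise. Includes a simulator for benchmark
    network pairs with known ortholog/analog/paralog structure, evaluation
    metrics (sensitivity, coverage, misalignment counts), utilities for building
    vertex similarity from tabular BLAST output and co-expression networks from
    expression compendia, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
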