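Package: irfnet
Title: Iterative Random Forests and Predictive Expression Networks
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Iterative Random Forest (iRF) with weighted candidate-feature
    sampling, grown from deterministically seeded sub-forests so results are
    identical for any worker partition. Provides the leave-one-out procedure
    (iRF-LOOP) that fits one iRF per gene and assembles the importance
    vectors into a directed, column-normalized adjacency matrix (a
    Predictive Expression Network), plus validation of thresholded networks
    against a Gene Ontology co-annotation network via intersect scores,
    node-label permutation nulls and t-statistics. Includes a Pearson
    co-expression comparator, SNP dosage filtering for eQTL-style runs, and
    seeded synthetic-data generators (planted regulatory networks,
    term-structured annotations, genotype panels) so every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    data.table,
    igraph,
    vcfR,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    ranger,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'irfnet-package.R'
    'classes.R'
    'forest.R'
    'irf.R'
    'loop.R'
    'go.R'
    'synthetic.R'
    'io.R'
    'cli.R'
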