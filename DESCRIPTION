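Package: primarypairs
Title: Prediction of Element-Transferring Reactant/Product Pairs in
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Predicts the element-transferring reactant/product pairs
    ("primary pairs") of metabolic reactions from reaction equations and
    compound formulas alone. Candidate pairs are scored by a weighted
    Jaccard similarity of chemical formulas, corrected by a per-compound-pair
    probability that is refined globally by iterative beta-binomial maximum
    a posteriori estimation until convergence. Includes chemical formula
    parsing and balance checking, reaction-set readers with the standard
    exclusion filters, confusion-matrix/MCC evaluation against reference
    pair annotations, a parameter grid search, ambiguity (score-tie)
    detection, bipartite metabolic graph construction with reaction-vertex
    replication for visualization, a bundled worked-example model, and a
    synthetic balanced-reaction generator with known ground-truth pairings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
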