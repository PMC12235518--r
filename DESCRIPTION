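Package: dicenet
Title: Differential Centrality-Ensemble Analysis of Condition-Specific
    Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Prioritizes condition-relevant genes by combining relaxed
    differential expression, information-gain feature selection,
    condition-specific correlation-weighted protein-protein interaction
    networks, differential betweenness and eigenvector centrality, and a
    rank-product ensemble score. Includes a synthetic two-condition
    expression simulator with planted network rewiring and planted
    differentially expressed genes, hypergeometric over-representation
    analysis against user-supplied gene sets, readers for expression,
    edge-list (STRING dialect) and GMT files, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
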