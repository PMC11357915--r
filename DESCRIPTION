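Package: tcmnet
Title: Network Medicine Analysis of Disease Modules, Drug Proximity and
    Herbal Ingredient Prioritization
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for network-medicine analysis of diseases, traditional
    medicine syndromes and multi-herb formulae on a protein-protein
    interaction network. Assembles and cleans interactomes from edge lists,
    computes the module separation score between gene sets, quantifies
    drug/formula-disease closest-distance proximity with degree-preserving
    permutation z-scores, ranks herbal ingredients by random walk with
    restart on a heterogeneous formula-herb-ingredient-protein network, and
    performs hypergeometric over-representation analysis. Ships a synthetic
    benchmark generator (scale-free interactomes, planted gene modules,
    placed target profiles, formula hierarchies with known actives) so the
    whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
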