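Package: CrossFeed
Title: Dynamic Flux Balance Analysis of Batch Co-Cultures and
    Diversity-Graph Discovery of Cross-Feeding Strain Communities
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates batch monocultures and multi-strain batch
    co-cultures of constraint-based metabolic models with a time-stepped
    (dynamic) flux balance analysis scheme in which independent
    competitors share a common, depleting substrate pool. From the
    by-product secretion profiles of single-gene-knockout strains it
    builds weighted "diversity graphs" whose edges quantify pairwise
    differences in by-production, compresses structurally redundant
    strains into supernodes, identifies candidate cross-feeding
    communities as cliques of the thresholded graph, and quantifies the
    growth benefit of simulated communities relative to their
    monocultures. Includes readers for BiGG-style JSON and SBML (fbc)
    models, gene-protein-reaction rule evaluation for knockout
    phenotypes, graph statistics (strength centrality, centralization,
    clustering, attribute assortativity), and generators for small
    analytically tractable cross-feeding fixture models.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    xml2,
    yaml,
    rlang
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    knitr
Config/testthat/edition: 3
biocViews: SystemsBiology, Metabolomics, GraphAndNetwork, Network
RoxygenNote: 7.3.3
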