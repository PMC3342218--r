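Package: mllayout
Title: Multilevel Force-Directed Layout and Semantic-Similarity Evaluation
    of Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Draws physical and genetic interaction networks with a
    multilevel force-directed layout: the graph is recursively coarsened by
    randomized weighted edge matching into a hierarchy of metanode graphs,
    then uncoarsened level by level with a node-weighted Fruchterman-Reingold
    refinement, optionally modulated by clustering coefficients to emphasise
    module separation. Includes exact metric spatial indexes (M-tree, uniform
    grid) for neighbour fetching, readers and writers for SIF/edge-list
    networks, TSV coordinate tables, OBO ontologies and GAF annotations, a
    Gene Ontology semantic-similarity evaluation of layout quality
    (distance-ranked similarity traces and a normalized score), and
    generators for hierarchically modular benchmark graphs with
    module-correlated annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    optparse,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
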