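Package: complexHier
Title: Hierarchical Organization of Protein Complex Evidence as a Directed Acyclic Graph
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Organizes experimental evidence for protein complexes (pull-down
    and co-fractionation associations) into a directed acyclic graph of
    approximate part-of relationships. Complexes are represented by protein
    weight functions under three schemes: support weights (fraction of
    evidences containing each protein), adjusted weights (support down-scaled
    for globally 'sticky' proteins occurring in more than the weighted-median
    number of complexes), and information-flow weights derived from damped
    random walks on the network of direct binary protein-protein interactions.
    Near-identical complex nodes are merged by agglomerative clustering under
    a weighted-overlap relative distance, small-effective-size nodes are
    filtered by participation ratio, and the resulting DAG is classified,
    decomposed into components, transitively reduced for display, and compared
    across weighting schemes. Includes a synthetic-corpus generator with
    planted nested complexes, redundant evidences, false positive/negative
    protein assignments and sticky proteins, together with recovery scoring
    against the planted hierarchy.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
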