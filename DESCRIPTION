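Package: hcmrank
Title: Heat-Conduction Ranking of Influential Spreaders in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies influential spreader nodes in undirected, unweighted
    networks with a heat-conduction importance score: each node's capacity to
    export "heat" to every other node is computed from its degree, the
    eigenvector-centrality gap to the receiver, the network density, the
    receiver's degree density, and the hop distance, and nodes are ranked by
    their mean output. The package also provides the structural baselines
    (degree, eigenvector, closeness, betweenness, k-shell), discrete-time SIR
    and independent-cascade spreading simulators with an exact bond-percolation
    oracle for small graphs, Kendall rank-agreement statistics against
    simulated spreading influence, and reproducible experiment drivers with a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
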