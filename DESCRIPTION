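Package: BoolSigNet
Title: Boolean Logic Modelling of Signalling Networks with Data-Driven
    Link Integration
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers Boolean logic models of signal transduction networks
    from perturbation experiments by combining literature-derived prior
    knowledge networks with strictly data-driven network inference.
    Implements effect-table based cause-effect inference (FEED) and
    mutual-information methods (ARACNe, CLR), compression of prior
    networks to their identifiable core, expansion into an AND/OR logic
    hypergraph superstructure, integration of inferred links with
    candidate mapping back to the uncompressed network, reliability
    weighting of integrated links by evidence-weighted shortest paths in
    a protein-protein interaction network, and genetic-algorithm training
    of the superstructure against data with separate size penalties for
    prior and integrated links. Includes a synthetic gold-standard
    generator and in-silico perturbation simulator for benchmarking.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: NetworkInference, Network, CellBasedAssays, Software
RoxygenNote: 7.3.3
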