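Package: grnmsb
Title: Gene Regulatory Network Ensembles at Mutation-Selection Balance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quasi-species dynamics of gene regulatory networks (GRNs) under
    the pathway framework, in which each gene's allele is an ordered
    (activator protein, product protein) pair and the phenotype is the
    reachable set of proteins from the environmental stimuli. The package
    enumerates the genotype space, builds genotype and neutral networks,
    computes the exact stationary distribution of GRNs at mutation-selection
    balance by power iteration on a matrix-free transition operator, derives
    its rare-mutation eigenvector-centrality limit, validates the analytic
    predictions against forward Wright-Fisher simulation, and identifies the
    structurally prevalent GRNs across environments and constraint groups.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
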