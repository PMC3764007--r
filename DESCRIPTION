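Package: spcnet
Title: Sparse Partial Correlation Networks for Epigenomic Signal Matrices
Version: 0.1.0
Authors@R:
    person("SPCN", "Maintainers", email = "spcnet@example.org", role = c("aut", "cre"))
Description: Infers sparse undirected networks of direct associations among
    epigenomic variables (histone modifications, chromatin accessibility,
    expression) measured over many genomic regions. Signal matrices are
    rank-transformed, partial correlations are obtained from the inverse
    correlation matrix, significance is assessed via the Fisher z-transform
    with control-adjusted degrees of freedom and Benjamini-Hochberg
    correction, and the network is sparsified by a cross-validated
    prediction-error criterion with a per-edge support vote. Also provides
    an explaining-away effect matrix, ranked pair-list overlap statistics
    (hypergeometric and Monte-Carlo nulls), consensus networks across
    conditions, a synthetic Gaussian graphical model generator, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
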