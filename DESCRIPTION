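Package: glyconet
Title: Gene Co-Expression Network Reconstruction for a Thermoanaerobic
    Glycobiome Microarray Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Reconstructs carbon-utilization ("glycobiome") gene
    co-expression networks from a substrate-by-growth-phase two-color
    microarray design. Provides replicate-based differential expression
    filtering of log2 ratios (|log2R| and |Z| cutoffs), Pearson
    correlation networks with a random-matrix-theory (RMT) threshold
    chosen from the nearest-neighbour eigenvalue spacing distribution
    (Poisson versus Wigner), fast greedy modularity community detection,
    and downstream module, hub, and growth-phase dynamics reports. A
    synthetic-data generator emulates the 33-array study layout with
    planted co-expression modules, hubs, negative-control probes and
    signal-to-noise dropout, providing ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
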