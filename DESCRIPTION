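Package: senet
Title: Structure-Entropy Node Importance Ranking for Undirected Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Ranks nodes of undirected, unweighted graphs by structure
    entropy: each node is scored by the edge-count-weighted Shannon entropy
    of the connected components left after its removal, so that small scores
    mark structurally critical nodes. Includes five benchmark centralities
    (degree, closeness, k-shell and an iterative variant, edge-weight sum,
    gravity model), four evaluation protocols (ranking monotonicity, rank
    CCDF, targeted-attack robustness, discrete-time SIR spreading), edge-list
    readers and writers for plain and Konect-style files, deterministic
    synthetic graph generators, and a command-line front-end.
License: MIT
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
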