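Package: cncgat
Title: Bifunctional lncRNA Classification with k-mer De Bruijn Graph
    Attention Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Identifies bifunctional (coding and non-coding) long non-coding
    RNAs from transcript sequence alone. Each transcript is converted into a
    weighted directed De Bruijn graph over its k-mers, node features are
    learned with a CBOW word2vec model over the k-mer corpus, and a
    multi-head graph attention network with a fully connected head scores
    bifunctional potential. Training uses stratified 5-fold cross-validation
    with early stopping and ensemble averaging. Interpretability utilities
    compute per-node attention entropy, entropy-frequency correlations,
    class rank shifts of k-mer entropy, attention-weight interaction
    networks with edge-percolated-component centrality, and motif enrichment
    tests. A synthetic transcript generator with planted Kozak-context open
    reading frames supports end-to-end benchmarking without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
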