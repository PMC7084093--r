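Package: trifound
Title: Triangle Foundations and Low-Rank Embedding Audits for Sparse Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Measures the low-degree triangle structure of sparse undirected
    graphs via the (c, Delta)-triangle foundation: the number of triangles
    contained among vertices of degree at most c, divided by the total vertex
    count. Builds d-dimensional spectral (eigendecomposition) embeddings of
    adjacency matrices, ingests node2vec-style embedding files, and constructs
    four dot-product edge-probability models (truncated dot product, logistic
    regression on the dot product, logistic regression on the Hadamard
    product, and degree-calibrated softmax). Samples Bernoulli graphs from
    these models and audits how much low-degree triangle structure the
    low-rank representation loses. Also provides numeric certificates for the
    rank lemma, the dot-sum balance inequality, the unit-vector packing lemma,
    and explicit rank lower bounds for triangle-rich graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
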