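Package: scgpcl
Title: Graph Prototypical Contrastive Learning for Single-Cell RNA-Seq Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Clusters cells in single-cell RNA sequencing count data by
    contrastive representation learning on a bipartite cell-gene graph.
    A two-layer GraphSAGE encoder is trained with an instance-wise InfoNCE
    loss, a prototypical contrastive loss over k-means prototypes, and a
    zero-inflated negative binomial reconstruction loss, then fine-tuned
    with DEC-style self-training (Student's-t soft assignments sharpened
    into a target distribution under a KL clustering loss). Includes a
    Splat-style synthetic count simulator with logistic dropout and
    ground-truth labels, clustering evaluation metrics (NMI, ARI,
    Hungarian-matched accuracy, macro/micro F1), readers and writers for
    dense and MatrixMarket count matrices, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    generics,
    ggplot2,
    jsonlite,
    methods,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
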