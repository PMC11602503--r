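Package: smmsn
Title: Self-Supervised Multi-Fusion Strategy Networks for Multi-Omics Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Deep clustering of patients from multiple omics views (e.g. mRNA
    expression, DNA methylation, miRNA expression) measured on the same
    samples. Each view is encoded by a stacked autoencoder (feature
    representation) and a graph convolutional network over a heat-kernel
    K-nearest-neighbour patient similarity graph (structural representation),
    with layer-wise joint-representation injection to counter GCN
    over-smoothing. Views are fused by an adaptive weighting network
    (softmax classification head) and by error-reconstruction fusion of the
    latent codes, and the fused model is trained end-to-end with a dual
    self-supervised Kullback-Leibler objective against a sharpened target
    distribution, yielding cluster labels per patient. Includes a synthetic
    multi-omics generator with known cluster structure, mapped clustering
    accuracy (optimal label assignment), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    mclust
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
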