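Package: metagrain
Title: Metacell Coarse-Graining and Sample-Weighted Statistics for
    Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Merges transcriptomically similar cells of a single-cell
    RNA-seq experiment into metacells at a tunable graining level by
    walktrap (or Louvain) community detection on a kNN/sNN graph built
    in PCA space. Provides size-weighted downstream statistics that
    treat each metacell as the number of cells it contains (weighted
    scaling, PCA via the weighted covariance SVD, Ward hierarchical
    clustering, silhouette, Welch t-test differential expression,
    Pearson correlation, signature scoring, AUC), evaluation metrics
    (metacell purity, rare-type weighted purity, adjusted Rand index,
    differential-expression recovery rate, GO match score of top
    correlated gene pairs, RNA-velocity purity and similarity),
    averaging of expression, spliced/unspliced layers and embeddings
    into metacell profiles, an approximate mode for large datasets,
    seeded synthetic-data generators, 10x-convention Matrix Market
    input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
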