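Package: scvalley
Title: Hashtag Demultiplexing by Histogram Valley Detection and a
    Single-Cell Analysis Pipeline
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Demultiplexes cell-hashing (hashtag oligo) droplet data by
    locating the valley after the initial slope of each smoothed per-hashtag
    count histogram via gradient descent, then assigns droplets to samples
    and flags cross-sample doublets. Around the demultiplexer it provides
    the downstream stages of a standard single-cell RNA-seq analysis:
    cell and gene quality control, log normalization, variable-gene
    selection, covariate-regressed scaling, PCA, shared-nearest-neighbor
    graph construction, Louvain clustering, expression-bin-matched module
    scores, and preranked gene-set enrichment with a permutation null.
    A negative-binomial droplet simulator with known ground truth makes
    the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    fgsea,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
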