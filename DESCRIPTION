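Package: psever
Title: Propagated Entry-Vector Embeddings of EHR Concepts on a
    Heterogeneous Knowledge Network
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Embeds electronic health record (EHR) concepts and patient
    cohorts onto a typed heterogeneous biomedical knowledge network using
    a cohort-weighted, topic-sensitive PageRank (random walk with
    restart). Restart mass re-enters the network through entry-point
    nodes (SEPs) according to patient-level concept co-occurrence encoded
    in a column-stochastic SEP transition matrix; the stationary rank
    vector of each walk is a propagated entry vector (PSEV), one element
    per network node. Includes z-score normalisation and per-node-type
    ranking of PSEV matrices, an edge-deletion/recovery benchmark with
    binomial and Fisher's-method statistics and three permutation nulls
    (Fisher-Yates node permutation, degree-preserving edge shuffling,
    patient-SEP shuffling), edge add-back learning curves, block
    enrichment permutation tests, shortest-path tracing of SEP
    contributions, and a seeded generator of synthetic knowledge graphs
    and patient tables with planted, recoverable disease-gene structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
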