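Package: expandnet
Title: Embedding-Based Search Term Expansion and Network Precision
    Evaluation for Social Video Corpora
Version: 0.1.0
Authors@R:
    person("Repo", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for discovering colloquial search terms around a technical
    health "focal term" and for auditing the retrieval they enable. Trains
    word2vec-style embeddings (CBOW or skip-gram with negative sampling) on
    short-video titles and descriptions, ranks nearest-neighbour vocabulary
    terms by cosine similarity, tabulates the recall improvement contributed
    by each expansion term, compares video sets with document-feature
    matrices, Euclidean set distances, chi-square keyness and complete-linkage
    clustering, and evaluates precision loss with cumulative
    precision/recall/F1 curves over degree thresholds on a platform
    relatedness graph. Includes a seeded generator of synthetic video corpora
    with planted vocabulary, relevance and graph structure, and a
    command-line pipeline for reproducible end-to-end runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ape,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
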