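Package: elclust
Title: Overlapping Community Detection by Extended Link Clustering
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects overlapping communities in undirected, unweighted
    networks by clustering links rather than nodes. Implements the extended
    link similarity (ELS), which scores both neighbor and non-neighbor link
    pairs from inclusive node neighborhoods, single-linkage hierarchical
    clustering of links, and dendrogram cut selection by maximal extended
    modularity (EQ). The baseline link-clustering variant (Jaccard
    similarity of neighbor links with a partition-density cut) is included,
    together with a quality-metric suite for overlapping covers (EQ,
    partition density, in-group proportion, coverage) and a planted
    four-community benchmark generator.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
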