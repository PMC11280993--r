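Package: ipgs
Title: Lossless Personalized Graph Summarization with Correction Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless summarization of large undirected graphs by greedy merging of
    nodes into super nodes under a correction-set representation: super edges plus
    positive (C+) and negative (C-) edge corrections allow exact reconstruction of the
    input graph. Candidate merge pairs are found with a weighted-Jaccard locality
    sensitive hashing scheme based on densified one-permutation hashing (DOPH) over
    integer-weighted neighborhood vectors. A personalized mode computes cumulative
    flow rates from user-specified target nodes and keeps the summary fine-grained
    around them. Includes compression-ratio accounting, synthetic graph generators
    for testing, GraphML/GML export for visualization tools, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
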