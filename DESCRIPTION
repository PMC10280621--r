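Package: parsclust
Title: Parsimonious Cladograms from Spanning Trees and Single-Linkage
    Dendrograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study maximum parsimony through the lens of
    hierarchical clustering. Builds parsimonious cladograms from minimum
    spanning trees of the Hamming graph of an aligned sequence set, runs
    single-linkage agglomerative clustering with an in-set labeling rule
    so the dendrogram doubles as a labeled cladogram, scores any labeled
    tree by its parsimony length, solves small parsimony on fixed
    (possibly multifurcating) topologies by uniform-cost dynamic
    programming, extracts flat clusterings from trees and compares them
    with F-scores, and ships brute-force oracles plus a sequence
    simulator for exhaustive verification at small scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
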