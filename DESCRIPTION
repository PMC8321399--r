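Package: hasgraph
Title: Reference-Free Short-Read Compression via Hamming-Shifting Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lossless compression of fixed-length genomic short reads without
    an external reference. Distinct reads are linked in a Hamming-shifting
    graph whose edges record the mismatching bases and the shifting offset of
    the best overlap between two reads; weight-lightest edges are detected by
    multiple rounds of k-minimizer and k-maximizer indexing, a minimum
    spanning forest is extracted with Kruskal's algorithm over a disjoint-set
    structure, and every non-root read is delta-encoded against its parent.
    Single-end and paired-end inputs are supported in order-free and
    order-preserving modes, together with the closed-form probability model
    for the detection of the lightest edges and a synthetic read simulator
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    Biostrings,
    optparse,
    jsonlite
Config/testthat/edition: 3
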