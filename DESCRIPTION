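Package: pgmap
Title: Seed-Chain-Extend Read Mapping to Pangenome Variation Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Maps long (and single-end short) sequencing reads to bidirected
    pangenome variation graphs with embedded haplotype walks. Implements the
    full seed-chain-extend pipeline at desk scale: snarl/chain decomposition
    of the graph, a minimum-distance index, weighted-minimizer seeding over
    haplotype sequences, zip-code trees for ordered seed-to-seed graph
    distances, two-pass co-linear chaining with a gap cost in the style of
    minimap2, and hybrid base-level alignment (wavefront alignment against
    haplotype spellings, banded global alignment against the graph, X-drop
    tail extension). Reads GFA v1.1 graphs, emits GAF alignments, and ships
    synthetic pangenome/read simulators plus mapping-accuracy evaluation so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
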