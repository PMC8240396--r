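Package: rfs2
Title: Exact Robinson-Foulds Supertrees of Two Binary Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Constructs an optimal Robinson-Foulds (equivalently, Split Fit)
    supertree of two unrooted binary phylogenetic trees with overlapping leaf
    sets, in polynomial time. The optimum is found by decomposing each source
    tree around the shared leaf set into a backbone tree plus attached extra
    subtrees, building a bipartite weighted incompatibility graph on the
    backbone bipartitions, extracting a maximum-weight independent set via
    min-cut, and refining an initial star supertree with the selected
    bipartitions. Also provides brute-force optimality oracles, seeded
    synthetic tree-pair generators, short-quartet utilities, a single-level
    divide-and-conquer merge pipeline, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    igraph,
    stats,
    utils,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
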