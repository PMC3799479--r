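Package: swapalign
Title: Local-Search Refinement of Global Protein Interaction Network Alignments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Refines global pairwise alignments of protein-protein interaction
    (PPI) networks by 2-Opt and 3-Opt edge swaps on an injective protein
    mapping, maximizing a convex combination of conserved-interaction count
    and sequence similarity. Starting from any initial mapping (for example a
    maximum-weight bipartite matching on BLAST bit scores), the refiner
    repeatedly applies strictly improving partner swaps drawn from per-vertex
    candidate sets until a local optimum is reached. Includes readers for edge
    lists, similarity tables, mappings, OBO ontologies and GAF annotations;
    alignment quality metrics (edge-correctness ratio and GO-based functional
    coherence); a geometric random graph generator and a planted-alignment
    simulator for robustness and recovery studies; and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
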