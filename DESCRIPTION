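Package: netenrich
Title: Neighborhood Enrichment Testing and Quality Control for Multiplexed Tissue Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Spatial cell-cell interaction statistics and quality-control tools for
    multiplexed tissue imaging. Implements the neighborhood enrichment test (NET), a
    permutation z-score for attraction or repulsion between cell types in which one
    type is held fixed and the other is re-drawn over the positions of the remaining
    cells, a conditional null that compensates for tissue structure. A conventional
    full-shuffle null is included for comparison. Also provides percentile
    Winsorization for aligning per-core staining-intensity features, confusion-matrix
    comparison of paired cell classifications with per-element cell selection, seeded
    generators for synthetic tissue maps and two-core feature tables, plain-CSV
    readers and writers for all tabular artifacts, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    graphics,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
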