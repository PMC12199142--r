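Package: rnalsc
Title: Local Stability Compensation Analysis for RNA Secondary Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Decomposes RNA secondary structures into stems, hairpin loops,
    bulges and internal loops, scores each component with Turner 2004
    nearest-neighbor free energies at 37 C, and computes the net free-energy
    statistic of local stability compensation (loop dG plus adjacent stem dG)
    together with its statistical controls over structure databases. Designs
    randomized RNA test libraries on a triply bulged hairpin template under
    composition, length and Hamming-distance constraints, and quantifies
    folding fidelity from DMS chemical-mapping reactivity via A/C-restricted
    AUROC in global, local and distal scopes, reactivity summaries and
    Hill-equation fits with the AUROC = 0.9 stability threshold. Includes a
    synthetic-data generator (linear loop-stem compensation databases and a
    two-state local-unfolding model for DMS reactivity) so the whole pipeline
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
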