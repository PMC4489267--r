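Package: BCMine
Title: Binet-Cauchy Fragment Mining over Protein Structure Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exhaustive mining of Calpha fragment conformations in
    collections of protein structures using the Binet-Cauchy (BC)
    geometric correlation score and a companion rigidity score. Provides
    sliding-window fragment search, mirror-conformation search,
    knowledge-based loop candidate retrieval anchored on four-residue
    flanks with a steric clash filter, and per-residue conformational
    specificity profiling, together with empirical P-value calibration,
    CSV hit reports, sequence-logo frequency matrices, a deterministic
    synthetic-structure generator for testing, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
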