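Package: pseudosym
Title: Internal Pseudosymmetry Detection and Homology Statistics for
    Membrane Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative tools for establishing internal two-fold (C2)
    pseudosymmetry in membrane-protein structures and for assessing remote
    homology between protein families. Provides C-alpha trace extraction
    from PDB/mmCIF, Kabsch superposition, an iterative sequence-independent
    TM-score structural aligner with common-core extraction, split-point
    scanning for duplicated halves, symmetry-axis and helix-tilt analysis,
    fold-connectivity combinatorics, percent-identity statistics with a
    shuffled permutation null and excess-identity estimation, entropy-based
    column conservation and sequence-logo information content, extreme-value
    (Gumbel) calibration of structure-search Z-scores with database-scale
    interpretation, Kyte-Doolittle hydropathy and membrane-topology
    profiling, and seeded synthetic-data generators for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
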