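Package: ebdiff
Title: Per-Residue Energy Breakdown Analysis for Protein Design Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Compares per-residue energy decompositions of a designed
    protein mutant against its reference structure. Parses score tables
    produced by per-residue energy-breakdown calculations, classifies
    every changed pairwise interaction into six presence/mutation
    categories and into physical interaction types (salt bridges,
    disulfide bonds, hydrogen-bond classes), computes total and
    significant interaction-energy changes, and joins per-residue net
    energies with residue depth below the molecular surface to localise
    stabilising and destabilising mutations. Includes a synthetic fixture
    generator (toy structures and mock breakdown tables with planted
    ground truth) and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    graphics,
    grDevices,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
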