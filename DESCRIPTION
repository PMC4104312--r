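Package: pinarch
Title: Structural Architecture and Evolution of PIN Auxin Efflux Carriers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates the tripartite architecture of PIN-FORMED (PIN)
    auxin efflux carriers (two transmembrane domains flanking a central
    intracellular loop) from protein sequences using conserved anchor
    motifs, builds per-position conservation profiles and consensus
    sequences on canonical coordinates (N1-N158, C1-C154), scans loops
    for an ordered library of conserved motifs and builds clade-level
    presence matrices, classifies proteins and clades as canonical,
    semicanonical or noncanonical, predicts the ten transmembrane
    helices from Kyte-Doolittle hydropathy with cryptic-peak recovery,
    and counts minimum independent origins of noncanonical structure on
    a clade cladogram.  A synthetic-family generator with full ground
    truth makes the whole pipeline testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
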