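Package: conserv3d
Title: Structure-Mapped Residue Conservation, Spatial Clusters and
    Aromatic Electron-Transfer Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Maps evolutionary conservation of a protein family onto 3D
    structures and interrogates the result. Computes per-column
    conservation from a multiple sequence alignment (sequence-weighted
    Jensen-Shannon divergence to a background amino-acid distribution,
    discretized to the familiar 9-grade scale), groups maximally
    conserved residues into spatial clusters on a structure, tabulates
    presence/absence coevolution of residue motifs across taxa, detects
    internal cavities by grid flood-fill, builds distance networks of
    redox-active aromatic residues (Tyr/Trp) compatible with
    electron-transfer hopping, and overlays population and pathogenic
    missense variants on the conservation clusters. Ships a planted-signal
    simulator (alignments, structures, variant tables) so every stage is
    testable without external downloads, plus fixtures transcribing the
    published frataxin/CyaY analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
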