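Package: rehydra
Title: Structural Recovery Analysis for Rehydrated Gas-Phase Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory ensemble analysis of protein compaction in vacuum and
    its reversal upon rehydration. Provides multi-model PDB trajectory and
    replica-set handling, Kabsch superposition with three RMSD reference
    schemes, concatenated-replica RMSF, projection-approximation collision
    cross sections, Shrake-Rupley solvent-accessible surface area, van der
    Waals envelope volumes, protein-solvent hydrogen-bond counting,
    residue-contact occupancy and difference maps, and a compaction report
    with per-condition means and rounded percent changes. A seeded synthetic
    replica generator with closed-form ground truth stands in for molecular
    dynamics so every stage runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
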