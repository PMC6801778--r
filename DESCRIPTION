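Package: memanchor
Title: Membrane and Lipid-Anchor Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing of all-atom membrane/protein molecular dynamics
    trajectories for peripheral membrane proteins anchored by isoprenoid
    (geranylgeranyl) chains. Computes bilayer structural observables
    (phosphate-plane thickness, area per lipid, acyl-chain order parameters
    S_CD and local order-deviation maps), lateral diffusion by jump distance
    analysis with mixture fitting and a mean-square-displacement cross-check,
    anchor insertion depth distributions, per-residue protein-membrane
    distances, radius of gyration, RMSF after Kabsch superposition, and
    G-domain orientation descriptors (pivot angle theta, internal dihedral
    omega). Includes synthetic-trajectory generators with planted ground
    truth (bilayers, Brownian tracks, anchored-protein poses) so every
    analysis can be validated by parameter recovery, plus PDB/GRO/DCD I/O
    and a selection mini-language.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    mclust,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
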