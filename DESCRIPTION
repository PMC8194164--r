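Package: targetfish
Title: Hybrid Ligand- and Structure-Based Protein Target Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Target fishing (inverse virtual screening) for small molecules.
    Candidate protein targets are shortlisted from a reference library of
    protein-ligand complexes by multi-fingerprint Tanimoto similarity to the
    co-crystallized ligands, docked poses are rescored against the reference
    structural interaction fingerprints, targets are ranked by a weighted
    combination of ligand and binding similarity, and binding activity
    (-log M) is predicted with class-specific random-forest models trained
    by repeated nested cross-validation. Includes a deterministic mock
    docking engine and synthetic-fixture generators so the whole workflow
    runs without external binaries or downloads. Molecule parsing and
    2D fingerprints are computed with RDKit through a bundled Python helper.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    ranger,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
SystemRequirements: Python (>= 3.8) with RDKit on PATH as 'python';
    Open Babel ('obabel') optional for hydrogen addition and PDBQT
    conversion; an AutoDock Vina compatible binary optional for real
    docking.
Config/testthat/edition: 3
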