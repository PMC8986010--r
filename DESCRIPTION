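Package: ppiscreen
Title: Interface Pharmacophore Screening and Trajectory Analysis for
    Protein-Protein Interaction Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based discovery workflow for small-molecule inhibitors
    of protein-protein interactions, built around the IL-6/IL-6R alpha site I
    interface. Derives 3D pharmacophore models from interface hot-spot
    residues, perceives and matches ligand features under essential/choice
    constraint logic, applies the Lipinski drug-likeness filter, measures
    trajectory stability (Kabsch RMSD/RMSF) and geometric contact occupancy
    (hydrogen bonds, salt bridges, hydrophobic and aromatic contacts), and
    decomposes binding free energies with a single-trajectory MM-GBSA model
    (GB-OBC1 polar term, Shrake-Rupley SASA nonpolar term). A synthetic-data
    generator builds toy interfaces, matching/decoy ligands, trajectories
    with planted contact schedules, and toy force-field parameters so every
    stage is testable without external structures or compound libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
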