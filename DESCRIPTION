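Package: PocketSwap
Title: Binding-Pocket Ligand Replacement and Redesign for Solute-Binding Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for swapping a bound ligand for a stereoisomer inside a
    protein binding pocket and redesigning the pocket around it. Provides
    PDB structure handling (monomer and heteroatom-ligand extraction),
    ideal-geometry construction of linear sugar alcohols (alditols) with
    explicit stereochemistry, rigid Kabsch superposition plus hydroxyl
    torsion refinement for backbone-guided ligand placement, geometric
    polar-contact (hydrogen-bond proxy) detection, a reduced all-atom
    energy model, fixed-backbone side-chain design by Metropolis simulated
    annealing over a rotamer library, torsion-space minimization and
    relax protocols, and the binding thermodynamic cycle (dG_bind and
    ddG_bind) used to judge whether a redesign is favorable. Includes a
    synthetic-structure generator that plants pockets with known contact
    geometry for validation, and an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
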