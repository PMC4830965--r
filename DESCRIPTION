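Package: gpcrTriage
Title: Structural Triage of Membrane Receptor Variants from Molecular
    Dynamics Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for membrane-embedded G protein-coupled
    receptor (GPCR) variant trajectories. Provides transmembrane-helix
    backbone RMSD via Kabsch superposition, chi1 side-chain dihedrals with
    rotamer-state classification and toggle-switch flip detection,
    Ballesteros-Weinstein residue numbering, lipid bilayer thickness maps
    and headgroup perturbation profiles from phosphate positions,
    grid-based binding-pocket volume tracking, local hydration counts,
    and a per-variant activating/damaging triage report. Includes a
    deterministic synthetic generator of receptor/bilayer systems and
    trajectories with programmable ground truth for validating every
    analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'model-core.R'
    'structure-metrics.R'
    'binding-site.R'
    'generator.R'
    'gpcrTriage-package.R'
    'membrane.R'
    'pdb-io.R'
    'report.R'
    'tsv-io.R'
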