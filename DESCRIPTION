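Package: StructTriage
Title: Structural Triage of Missense Variants on Experimental Protein Structures
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Assesses the structural impact of missense variants on
    experimental protein structures. Builds repacked wild-type and mutant
    side-chain models on a fixed backbone, evaluates eleven thresholded
    structural-damage rules (solvent accessibility switches, salt-bridge and
    disulfide breakage, torsion-angle compatibility, buried-charge changes,
    steric clashes, buried hydrophobic-to-hydrophilic substitutions,
    proline introduction, buried-glycine replacement, sharp-turn glycine
    replacement, and cavity-volume changes), combines external in-silico
    predictor verdicts into consensus calls, and reports cohort-level
    contingency statistics. Includes deterministic synthetic-structure and
    synthetic-cohort generators so the full pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
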