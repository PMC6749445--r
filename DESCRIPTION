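Package: strainscope
Title: Geometric Strain Analysis for Ultrahigh-Resolution Protein Structures
Version: 0.1.0
Authors@R:
    person("P2", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Residue-specific side-chain planarity ("bending") angles, peptide-bond
    omega non-planarity, weak C-H...O hydrogen-bond detection with secondary-structure
    capping classification, and anisotropic displacement (ADP) eigen-analysis for
    protein coordinate files in PDB and mmCIF formats. Includes a synthetic-structure
    generator that builds ideal and controllably distorted residues, secondary-structure
    elements and ADP tensors with exactly known ground truth, and a command-line
    pipeline for single-structure and batch comparative scans.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
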