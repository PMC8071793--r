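Package: fdapls
Title: Lipid-Protein Force Distribution Analysis with Partial Least
    Squares Functional Mode Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to relate lipid-protein interaction forces to
    conformational state in membrane proteins.  Computes short-range
    nonbonded forces (truncated Coulomb plus force-switched
    Lennard-Jones) between protein residues and lipid molecules and
    reduces them to a per-residue punctual stress, quantifies
    conformational state through the projection onto the difference
    vector between two reference structures after least-squares
    superposition, and regresses the observable on the per-residue
    stress vector with partial-least-squares functional mode analysis
    (PLS1/NIPALS).  Includes leave-one-trajectory-out cross-validation
    with ROC AUC, Pearson correlation and false-positive metrics,
    force-hotspot ranking, chain-symmetry diagnostics, and a synthetic
    data generator for toy membrane-protein systems and force
    ensembles with a known latent transition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    bio3d,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    yaml
Config/testthat/edition: 3
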