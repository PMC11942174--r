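Package: katpscreen
Title: Virtual-Screen Triage, Rb+ Efflux Dose-Response and Binding-Pocket
    Dynamics for KATP Pharmacochaperone Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for potassium ATP (KATP) channel
    pharmacochaperone discovery campaigns. Implements the post-scoring
    virtual-screen triage funnel (known-binder novelty filtering by Tanimoto
    similarity, score ranking, Butina sphere-exclusion diversity clustering,
    property filters and candidate selection), rubidium efflux assay
    quantification with variable-slope four-parameter Hill inhibition fits
    and IC50 reporting, molecular-dynamics binding-pocket analysis
    (Kabsch superposition onto pocket C-alpha atoms, ligand-fragment
    centre-of-mass mobility, residue contact-frequency identification), and
    HOLE-style spherical-probe pore-radius profiling. Every stage is backed
    by synthetic-data generators with known ground truth so the full
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    multcomp,
    bio3d,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
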