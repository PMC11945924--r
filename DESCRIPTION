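Package: comsia
Title: Comparative Molecular Similarity Indices Analysis (CoMSIA) 3D-QSAR
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete grid-based 3D-QSAR workflow in the CoMSIA
    (Comparative Molecular Similarity Indices Analysis) tradition. Reads
    pre-aligned molecules with activities from MDL SDF files (or unaligned
    molecules as SMILES, aligned on their maximum common substructure),
    computes Gaussian similarity-index fields (steric, electrostatic,
    hydrophobic, hydrogen-bond donor and acceptor) on a shared Cartesian
    lattice, builds partial least squares regression models with
    leave-one-out cross-validated component selection (q2, PRESS, S_PRESS,
    r2, S, per-field contributions), and extracts percentile-thresholded
    isosurface contour maps from the PLS coefficients for rational design.
    Includes a deterministic synthetic fixture generator so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    jsonlite,
    mixOmics,
    optparse,
    testthat (>= 3.0.0),
    withr
SystemRequirements: OpenBabel (the 'obabel' executable on PATH) for
    partial-charge assignment, SMILES parsing and 3D embedding.
Config/testthat/edition: 3
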