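Package: helicalem
Title: Helical Cryo-EM Reconstruction, Flexible Fitting and Actomyosin Structure Comparison
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale toolkit for helical cryo-EM image analysis of actin
    filaments decorated with myosin motor domains. Generates synthetic
    filament specimens (pseudo-atomic helices, CTF-modulated noisy
    projections, windowed segment stacks with ground truth), performs
    iterative helical real-space reconstruction with gold-standard
    half-datasets and helical rise/twist search, estimates map resolution by
    Fourier shell correlation with B-factor sharpening and cylindrical-mask
    local-resolution series, flexibly fits atomic models into density maps
    under per-atom coupling regimes and helical symmetry restraints, and
    quantifies conformational differences between actomyosin states (Kabsch
    superposition, per-residue and domain RMSD, centroid displacements,
    displacement-vector fields, rotation axis/angle, sequence-conservation
    mapping onto structures).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    jsonlite,
    bio3d,
    seqinr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
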