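Package: dicckit
Title: Inter-Domain Distance Correlation and Disulfide-Bond Quantification
    for Multi-Domain Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of inter-domain protein dynamics and of
    engineered disulfide bonds. Computes backbone RMSD series and distance
    correlation coefficients (DiCC) between domain motions from structural
    trajectories (multi-model PDB), with Kabsch superposition, replica
    averaging, and Table-style matrix output. Provides peptide mass
    arithmetic for disulfide-linked species (monoisotopic masses, m/z,
    electron-transfer-dissociation fragment masses, isotope envelopes) and
    quantifies the disulfide-protected fraction of an engineered cysteine
    from heavy/light iodoacetamide labeling by non-negative least squares.
    A synthetic-data module generates trajectories with controlled
    inter-domain coupling and labeled-peptide peak lists with known
    protection fractions so that every analysis stage has a ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
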