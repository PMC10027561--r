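Package: scLipidFlow
Title: Single-Cell Shotgun Lipidomics of Phosphatidylcholine and
    Sphingomyelin Species
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for single-cell shotgun lipidomics by direct-infusion
    precursor ion scanning of the phosphocholine head group (m/z 184).
    Covers the full computational chain from per-well spectra to per-cell
    relative quantities: sum-composition lipid chemistry (name parsing,
    elemental formulas, [M+H]+ m/z, isotope envelopes), a plate simulator
    that renders FACS-style 96-well experiments with ground truth,
    spectrum processing (smoothing, robust noise estimation, peak
    picking, 0.5 Da target matching, M+2 deisotoping, intensity and
    signal-to-noise filters), extraction-blank subtraction and
    internal-standard quantification to fmol, and single-cell
    heterogeneity analytics (CV-versus-mean regression with confidence-
    interval outlier calling, Welch comparisons, PCA and t-SNE).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    Rtsne,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    cluster,
    mzR
biocViews: Lipidomics, MassSpectrometry, SingleCell, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
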