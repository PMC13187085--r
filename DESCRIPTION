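Package: cytonuclear
Title: Cytonuclear Effect Mapping, NIRS Calibration and Phenomics Divergence for Reciprocal Crosses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying maternally inherited (cytoplasmic) effects on
    quantitative traits in reciprocal cross populations. Provides synthetic data
    generators for reciprocal F2 populations, near-infrared (NIR) spectra and
    multi-day phenomics series with known ground truth; a chemometric calibration
    workflow (spectral pretreatments, robust spectral outlier consensus,
    Kennard-Stone sample selection, partial least squares regression with repeated
    cross-validation and one-sigma component selection); derived grain composition
    traits; Type III ANOVA engines for cytoplasm-by-environment and
    marker-by-cytoplasm-by-environment models with eta-squared effect sizes,
    noncentral-F confidence bounds and a three-condition significance gate; and a
    weighted Cohen's d divergence score for comparing cytoplasmic effects between
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    signal
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite
Config/testthat/edition: 3
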