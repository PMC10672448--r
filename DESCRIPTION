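Package: epilichen
Title: Epiphytic Lichen Biomonitoring Indices and NIR Aquaphotomics Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Long-term biomonitoring of air quality with epiphytic lichens:
    the Index of Atmospheric Purity (IAP) at tree and station level, a
    semi-quantitative 1-5 Damage Index (DI) with a max-over-symptoms rule,
    between-campaign comparisons (Student's t, frequency-change matrices,
    NMDS ordination) and trait models linking community change to ecological
    indicator values. Includes an aquaphotomics chemometric pipeline for
    Vis-NIR thallus spectra: water-band (1300-1600 nm) selection,
    multiplicative scatter correction, mean centring, PCA, and PLS-DA with
    cross-validated latent-variable selection reporting per-class
    sensitivity, specificity and balanced classification error. Ships
    simulators for community surveys, damage records, air-quality series and
    class-structured NIR spectra with known ground truth, so every stage is
    testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
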