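Package: ramanSDI
Title: Label-Free Raman Assessment of Sperm DNA Integrity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric pipeline for classifying sperm DNA integrity from
    single-cell Raman spectra acquired on glass slides.  Implements iterative
    peak-excluding polynomial (Vancouver-style) fluorescence baseline removal,
    Savitzky-Golay smoothing, vector normalization, extended multiplicative
    signal correction (EMSC) against glass and agarose interferent spectra,
    PCA with t-test-based component selection, two-class linear discriminant
    analysis, PLS-DA, grouped leave-one-out and k-fold cross-validation with
    sensitivity/specificity/ROC/AUC, and band-intensity Raman mapping.  A
    seeded synthetic-spectrum generator emulating sperm-on-glass cohorts and
    mapping phantoms provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
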