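Package: xicquant
Title: Targeted Label-Free Quantification of Phosphopeptides from MS1
    Extracted Ion Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identification-driven, label-free quantification of modified
    peptides from centroided MS1 spectra. Computes elemental compositions,
    monoisotopic masses and theoretical isotope envelopes for modified
    peptides; extracts ion chromatograms (XICs) for the first three isotopes
    of each peptide ion under m/z, retention-time, charge and
    isotope-distribution constraints; quantifies chromatographic peaks by
    apex height and trapezoidal area; normalizes intensity matrices to total
    chromatogram intensity and to percent-of-maximum; flags outlier
    replicates; and evaluates quantification quality as precision
    (coefficient of variation), dilution-series linearity (R squared with a
    small-sample significance threshold) and accuracy (percent deviation
    from the per-peptide regression). A synthetic LC-MS1 run generator with
    ground-truth ledgers makes the whole pipeline testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    mzR,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
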