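Package: etquant
Title: Automated Quantification for LC-MS(n) Emergency-Toxicology Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantification engine for a broad LC-MS(n) emergency-toxicology
    screen of drugs and active metabolites in blood plasma. Implements weighted
    least-squares calibration with data-driven weighting selection and Mandel
    linearity testing, an electronically stored five-point calibration with
    one-point slope recalibration and QC-drift monitoring, GTFCh/EMA validation
    statistics (matrix effects, within- and between-run accuracy and precision,
    co-elution ionization effects, carry-over, selectivity), censored
    quantification with therapeutic/toxic interpretation, and censoring-aware
    proficiency-test adjudication. Includes a seeded generator of synthetic
    peak-area data for end-to-end testing without instrument access.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
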