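Package: pibquant
Title: Reference-Region Quantification of [11C]PiB Amyloid PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Kinetic quantification of dynamic [11C]PiB amyloid PET from
    regional time-activity curves: the plasma-input reversible two-tissue
    compartment model with blood volume (2T4k_Vb), reference Logan graphical
    analysis, the simplified reference tissue model (SRTM) and standardized
    uptake value ratios (SUVr), evaluated against the plasma-input gold
    standard for five candidate reference regions. Includes test-retest,
    Bland-Altman agreement, longitudinal-stability and group-discrimination
    statistics, and a synthetic dynamic-scan cohort generator for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
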