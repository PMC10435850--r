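Package: swallowsound
Title: Swallowing Sound Quantification from Cervical Auscultation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies swallowing sounds recorded with an electronic
    stethoscope during water-swallow trials. Frames the auscultation
    section on a 12-ms grid, extracts a 148-dimension acoustic feature
    vector per frame (mel band energies, liftered cepstra, local band
    variance and scalar spectral descriptors), classifies frames as
    fine-crackle (bolus inflow) sound with an AdaBoost-derived linear
    discriminant, and aggregates decisions into per-second fine-crackle
    quantitative values (FCQV), a per-trial index and the max-over-trials
    swallowing sound index. Includes a seeded synthetic generator of
    labeled crackle-burst recordings and patient cohorts, plus the study
    statistics layer: group comparisons, univariate screening,
    age-adjusted models, ROC cutoff selection and two-sample t-test
    sample-size computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
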