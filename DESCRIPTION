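Package: expoband
Title: Semi-Quantitative Near-Field Occupational Exposure Scoring and Model Evaluation
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Computes a semi-quantitative exposure score for occupational
    inhalation exposure situations from twelve classified modifying factors
    (job position, emission potential, historical exposure, process type,
    ventilation and containment, localized controls, personal protective
    equipment, health hazard, task duration and frequency, distance from the
    source, and room volume), assigns one of four exposure categories from the
    log-transformed score, and provides lognormal exposure statistics
    (geometric mean, geometric standard deviation, closed-form 90th
    percentile, pooled summaries, exceedance) together with model-evaluation
    statistics (bias, relative bias, precision, mean absolute error,
    Bland-Altman limits of agreement, log-scale Pearson correlation) for
    comparing exposure-model estimates against personal measurements, either
    on individual data or reconstructed exactly from grouped summaries.
    Ships the factor-score lookup as a versioned configuration file, a
    bundled styrene validation dataset for fiberglass-reinforced-plastics
    lamination and inspection tasks, a seeded lognormal measurement
    simulator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
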