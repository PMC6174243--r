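Package: alphanorm
Title: Resting-State EEG Alpha Biomarkers with Age-Normative Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reproducible pipeline for extracting individual alpha-peak
    characteristics (frequency and power) from resting-state EEG recorded
    under eyes-closed/eyes-open conditions, and for placing them on an
    age-normative chart. Includes EDF+ reading and writing, powerline comb
    filtering, signal-quality based bad-channel detection with spherical
    spline interpolation, sliding-window spectral estimation, alpha peak
    detection on the eyes-closed minus eyes-open difference spectrum,
    locally weighted (tricube kernel) normative curves of alpha
    characteristics against age with deviation scores, case-control
    variance-heterogeneity and outlier-proportion tests, inter-rater
    agreement, ANOVA and brain-volume regressions, plus a synthetic
    EEG/cohort generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
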