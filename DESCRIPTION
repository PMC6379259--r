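Package: bowlearn
Title: Sound-Quality and EEG Biomarkers of Violin Bowing Practice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the quality of bowed open-string violin tones with
    Yin-derived descriptors (pitch instability, dynamic instability,
    aperiodicity) and a standardized Sound-instability composite, and tracks
    motor learning in 14-channel consumer EEG via Welch band power over
    10-20 electrode clusters, modified Z-score outlier masking, and
    event-related desynchronization (ERD/ERS) relative to a baseline block
    of trials. Includes information-gain feature ranking with MDL
    discretization, the nonparametric test battery used to compare learner
    groups, a deterministic synthetic cohort generator (audio plus EEG with
    programmed group and block structure), and a manifest-driven pipeline
    that produces plot-ready result tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
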