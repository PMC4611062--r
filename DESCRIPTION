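Package: tvpac
Title: Time-Varying Phase-Amplitude Coupling Biomarkers for Event-Related EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates event-related cross-frequency coupling from multi-trial
    single-sensor EEG epochs. Implements a two-stage Hilbert phase-amplitude
    coupling (PAC) estimator, across-trial time-varying phase-locking values at
    full resolution or in non-overlapping stepping windows, directed
    cross-frequency contrast graphs between conditions and groups,
    bootstrap-stabilised Wilcoxon rank-sum feature ranking, and linear
    support-vector-machine biomarkers validated by leave-one-out and repeated
    split cross-validation (with a leakage-controlled nested mode). Includes
    competing spectro-temporal representations (time-locked averages, STFT
    spectrograms, Morlet scalograms) that flow through the same ranking and
    classification pipeline, and an oddball-like synthetic cohort generator
    with ground-truth coupling structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    class,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
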