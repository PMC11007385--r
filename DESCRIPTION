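Package: somnopark
Title: Sleep-Wake Scoring and Parkinsonian State Recognition from Rodent
    ECoG/EMG Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epoch-wise analysis of rodent electrocorticography (ECoG) and
    electromyography (EMG) recordings for automatic vigilance-state scoring
    (WAKE, NREM, REM) and recognition of the 6-OHDA parkinsonian state.
    Provides a synthetic polysomnography cohort generator with controllable
    state-dependent band amplitudes and corticomuscular coupling; per-epoch
    spectral band-power, EMG-amplitude and magnitude-squared-coherence
    features; nonparametric feature screening (Kolmogorov-Smirnov,
    Kruskal-Wallis with Dunn post hoc, Mann-Whitney U); RBF-kernel support
    vector machine classifiers under leave-rats-out protocols; and confusion
    matrix, precision/sensitivity/specificity, Cohen's kappa and ROC/AUC
    evaluation. Reads and writes EDF, CSV hypnograms/feature tables, and JSON
    configurations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
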