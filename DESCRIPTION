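Package: medconn
Title: Inter-Hemispheric EEG Connectivity Analysis of Meditation States
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for band-limited inter-hemispheric functional
    connectivity analysis of multichannel EEG recorded across meditation
    states. Generates synthetic cohorts of coupled narrowband signals with
    group- and state-dependent inter-hemispheric coupling, decomposes signals
    into the canonical delta/theta/alpha/beta bands with zero-phase
    Butterworth filters, computes Pearson correlation and Hilbert-phase
    locking value matrices, derives weighted graph metrics (Onnela clustering
    coefficient, characteristic path length via Dijkstra shortest paths),
    assembles state-wise and band-wise feature tables, and compares six
    classifier families under 10-fold cross-validation with subject-level
    folds. Between-group contrasts use Welch tests on subject-level means.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    class,
    rpart,
    randomForest,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
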