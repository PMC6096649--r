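Package: crossfreq
Title: Cross-Frequency Coupling Analysis of EEG Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimation of delta-beta cross-frequency coupling in epoched
    EEG: debiased phase-amplitude coupling (dPAC) with phase-clustering
    correction, epoch-shuffled surrogate nulls and Z-scores, and
    within-subject amplitude-envelope correlation (AAC). Includes the full
    preprocessing chain (decimation, zero-phase Butterworth band-pass
    filtering realized as cascaded second-order sections, Hilbert analytic
    signal, edge trimming), a synthetic nested-oscillation EEG generator
    with controllable coupling depth, envelope correlation and
    phase-clustering bias, a nonparametric statistics layer (Wilcoxon
    signed-rank, Mann-Whitney U, Spearman rho, Benjamini-Yekutieli FDR),
    and a cohort-level study pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
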