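Package: proxhrv
Title: Interpersonal Distance and Short-Window Heart Rate Variability Analysis
Version: 0.1.0
Authors@R:
    person("Kata", "Molnar", email = "kmolnar@example.org", role = c("aut", "cre"))
Description: Measurement-and-analysis chain for stop-distance (proxemics)
    experiments with concurrent heart-rate-variability recording. Provides a
    synthetic session generator for the eight-episode approach paradigm,
    readers for plain-text RR-interval exports and proximity traces, per-beat
    timestamp reconstruction, median-per-second resampling, RR artifact
    correction, windowed and ultra-short-term (10 s) RMSSD, stop-distance
    condition extraction with active/passive pooling, and a frequentist
    statistics battery: mixed-design ANOVA/ANCOVA with partial eta squared,
    Bonferroni post hocs, Mann-Whitney with rank-biserial correlation,
    chi-square, Spearman correlations with Benjamini-Hochberg FDR,
    case-resampling bootstrap regression, and simulation-based power.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
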