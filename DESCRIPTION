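Package: rovingmmn
Title: Roving-Oddball Stimulus Generation and MMN/P3a Analysis for
    Harmonicity EEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the effect of tone harmonicity on auditory
    prediction-error responses. Synthesizes harmonic and frequency-jittered
    (inharmonic) complex tones with BS.1770 loudness normalization, generates
    roving-oddball event sequences with deviant-order and frequency-shift
    labels, quantifies stimulus regularity with approximate entropy, simulates
    multi-participant epoched EEG with N1/P2, MMN, P3a and ORN components,
    and runs the full ERP statistical chain: difference waves, peak measures,
    spatio-temporal cluster-based permutation tests (paired t and
    repeated-measures F), balanced repeated-measures ANOVA with Tukey HSD
    contrasts, and a-priori power simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    emmeans,
    optparse
Config/testthat/edition: 3
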