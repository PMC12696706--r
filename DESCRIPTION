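Package: docbci
Title: Spectral EEG Analysis and Closed-Loop Motor-Imagery BCI Simulation
    for Disorders of Consciousness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multichannel EEG from patients with prolonged
    disorders of consciousness undergoing closed-loop motor-imagery
    brain-computer interface (MI-BCI) training. Provides a synthetic-EEG
    cohort generator for unresponsive-wakefulness and minimally-conscious
    virtual subjects; a preprocessing chain (Butterworth band-pass and notch
    filtering via second-order sections, sub-band decomposition, bad-channel
    interpolation, ICA-based ocular artifact attenuation, common average
    referencing, 5-s epoch screening and a task/baseline SNR gauge); Welch
    relative band-power estimation aggregated by cortical region; a
    beta/alpha attention-index BCI engine with threshold-gated trial scoring;
    the matching nonparametric statistical battery (Wilcoxon rank-sum and
    signed-rank, Welch t, Pearson chi-square, Spearman correlation with
    bootstrap intervals); and a reproducible end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
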