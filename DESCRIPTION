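Package: renyieeg
Title: Wavelet Renyi Entropy Analysis of Prefrontal EEG for Mental Fatigue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pipeline for quantifying mental fatigue from resting-state
    prefrontal EEG using the normalized order-2 Renyi entropy of relative
    wavelet energies. Implements band-pass preprocessing, overlapping
    epoching, a periodized Daubechies-4 discrete wavelet transform with
    in-band threshold denoising, wavelet band energies and Renyi entropy,
    oddball reaction-time extraction, and a repeated-measures inference
    layer (Mauchly sphericity, Greenhouse-Geisser corrected within-subject
    ANOVA, LSD post-hoc contrasts, Pearson correlation). A seeded synthetic
    cohort generator emulates a multi-day competition study so the full
    chain is testable without access to raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    signal,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
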