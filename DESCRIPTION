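Package: pcgbeat
Title: Heartbeat Detection from Phonocardiograms with ECG-Anchored Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the first and second heart sounds (S1, S2) in
    phonocardiogram (PCG) recordings and estimates heart rate from the
    detected beats.  The detector band-pass filters and wavelet-denoises the
    acoustic signal, computes a third-order Shannon-energy envelope,
    picks envelope peaks with a dual-threshold scheme, classifies
    inter-peak intervals into systole/diastole/longer by one-dimensional
    K-means seeded from the presumed heart period, and confirms or recovers
    beats with interval-ratio rules.  A reference-ECG branch detects and
    corrects R peaks and locates T-wave maxima, which anchor per-beat
    scoring windows for sensitivity and positive predictive value.  A
    seeded simulator generates PCG+ECG recordings with ground-truth
    annotations so the whole pipeline can be validated without clinical
    data.  Readers and writers for WAV, CSV and WFDB-style records and for
    annotation tracks are included, together with a small command-line
    front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
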