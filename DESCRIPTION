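Package: ridergait
Title: Horse-Riding Gait Classification with Ensemble Stacked Auto-Encoders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Classifies four horse-riding gaits (walk, sitting trot, rising trot,
    canter) from 8-channel rider-motion time series. Provides a synthetic
    gait-signal generator, orthogonal wavelet-packet compression with periodized
    filter banks, windowed statistical featurization (five statistics over
    non-overlapping 20-frame windows), from-scratch stacked auto-encoders with
    greedy layerwise pretraining, softmax heads and supervised fine-tuning, and
    probability-level ensemble fusion by the sum and product rules, together with
    stratified evaluation utilities and an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
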