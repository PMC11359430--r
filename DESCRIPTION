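Package: ppgaf
Title: Atrial Fibrillation Detection from Long-Term Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects atrial fibrillation (AF) in long-term single-channel
    photoplethysmography (PPG) recordings. Provides a synthetic PPG generator
    with normal-sinus-rhythm and AF rhythm models, peak-anchored two-minute
    segmentation, empirical mode decomposition (EMD) together with its
    ensemble (EEMD) and complementary-ensemble (CEEMD) variants,
    correlation-based intrinsic mode function selection, power-normalized
    Gammatone filterbank feature extraction with appended inter-beat-interval
    statistics, a bidirectional long short-term memory (BiLSTM) classifier
    trained with Adam and a step learning-rate schedule (including a
    learning-rate range test), and an evaluation suite with confusion
    matrices, recall, precision, F-measure and the combined ET-score that
    weights F-measures by a computation-speed rank factor.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
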