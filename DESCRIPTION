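Package: eegtw
Title: Time-Window EEG Emotion Recognition with Experiment-Level Batch Normalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Band-wise power spectral density and differential entropy feature
    extraction from epoched multichannel EEG, linear-dynamic-system smoothing,
    time-window aggregation at eleven window lengths, experiment-level min-max
    batch normalization (ELBN), multi-classifier offline emotion recognition on
    fixed trial splits, sliding-window online recognition, and channel-by-band
    Kruskal-Wallis sensitivity analysis. Ships a SEED-structured synthetic EEG
    generator with known class structure and controllable inter-session drift
    so the whole pipeline is testable without access to the gated dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    glmnet,
    e1071,
    class,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
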