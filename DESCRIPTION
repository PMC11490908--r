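Package: gatefusion
Title: Gated Multimodal Fusion for Depression Detection from Clinical Interviews
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting psychological distress (depression) from
    multimodal clinical-interview sessions in the DAIC-WOZ style: timestamped
    transcripts, framewise audio features (74 per 10 ms frame) and framewise
    video features (388 per frame). Provides a synthetic cohort generator that
    reproduces the corpus shell (189 sessions, 7:3 class imbalance, 7-33 minute
    durations) with controllable per-modality class signal; sentence-level
    alignment of the three modalities into fixed-length sequence tensors;
    minority-class upsampling; a gated fusion network built from highway-style
    gating blocks with per-timestep biases, per-modality projections to a
    common width, time-axis concatenation and a recurrent head, with exact
    trainable-parameter accounting; classical per-modality classifiers (SVM,
    random forest), six-layer convolutional baselines, LSTM/BiLSTM variants
    with sentence- and word-level gating; stacked late fusion through a
    second-stage SVM on out-of-fold scores; and a precision/recall/F1
    evaluation harness with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
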