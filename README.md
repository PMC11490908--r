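# gatefusion

Multimodal detection of psychological distress (depression) from clinical
interview sessions, in the style of the DAIC-WOZ corpus: timestamped
transcripts, framewise audio features (74 per 10 ms frame) and framewise
video features (388 per frame), with one binary label per session.

The package is aimed at researchers in computational psychiatry who want to
study *how* multimodal fusion architectures behave — alignment conventions,
gating, late fusion, class balancing — without access to the licensed corpus.
A synthetic cohort generator reproduces the corpus's statistical shell
(189 sessions, 59 depressed / 130 non-depressed, 7–33 minute interviews)
with controllable per-modality class signal, so every claim about the
pipeline can be tested end to end.

## The model

Each session is aligned at the sentence level: every participant utterance
becomes one time step whose audio/video vector is the per-feature mean over
the utterance's timestamp window in the frame tables, and whose text vector
is the mean 300-d token embedding concatenated with the token count (301-d).
Sequences are zero-padded or truncated to a fixed length L (default 1700).

The gated fusion network applies, per modality:

- **video** (L×388): three stacked highway-style gating blocks, then dense
  projections 388 → 200 → 74;
- **audio** (L×74): three gating blocks, then a dense 74 → 74 projection;
- **text** (L×301): dense projections 301 → 150 → 74 (no gating).

A gating block computes, per time step *t*,

```
g_t = sigmoid(x_t W_G + b_G[t])          # gate
h_t = relu(x_t W_T + b_T[t])             # transform
out_t = g_t ⊙ h_t + (1 − g_t) ⊙ x_t      # gated carry
```

with d×d weight matrices and *per-timestep* L×d biases, so one block holds
`2·(d² + L·d)` trainable scalars — 1,620,288 at d = 388 and 262,552 at
d = 74 for L = 1700. The three projected streams are concatenated **along
the time axis** (order audio, video, text) into a 3L×74 = 5100×74 sequence,
consumed by an LSTM (128 units, `4·128·(74+128+1)` = 103,936 parameters)
whose last state feeds a single logistic output (129 parameters). The full
network counts 5,907,283 trainable parameters; `count_parameters()` prints
the per-layer account. Training is minibatch Adam on binary cross-entropy.

Comparison models mirror the usual baselines: per-modality SVM / random
forest on session-level summary features (TF-IDF + lexical statistics for
text; per-feature mean and SD for audio/video), six-layer CNNs (2-D
convolutions over the text grid, 1-D along time for audio/video), LSTM /
BiLSTM variants with sentence- or word-level gating, and stacked late
fusion: a second-stage SVM trained on out-of-fold first-stage scores.

All neural components (gating blocks, LSTM/BiLSTM, convolutions, Adam) are
implemented in base R on BLAS matrix operations, with hand-derived
backpropagation verified against finite differences in the test suite.

## Worked example

```r
library(gatefusion)

## a desk-scale cohort: 12 sessions, strong audio signal
spec <- cohort_spec(n_sessions = 12, depressed_fraction = 0.5,
                    duration_range = c(30, 60), seed = 7)
sig  <- signal_model(audio_shift = rep(2, 74), video_shift = 0)
idx  <- generate_cohort(spec, sig)
ground_truth_summary(idx)$class_counts
#> non_depressed     depressed
#>             6             6

bundles <- materialize_cohort(idx)
aligned <- align_cohort(bundles, L = 20)
fit <- train_fusion(fusion_network(network_spec(L = 20, units = 16, seed = 3)),
                    aligned$sessions, epochs = 10, batch_size = 4,
                    lr = 3e-3, seed = 5)
tail(fit$history, 1)
#>    epoch      loss accuracy
#> 10    10 0.5108107        1

pred <- predict(fit, aligned$sessions)
evaluate_predictions(pred$call, idx$label, model = "gated-fusion")
#>         model modality precision recall f1 accuracy  n       split
#>  gated-fusion      all         1      1  1        1 12 unspecified
```

The final row reads: on this strongly separable synthetic cohort the fusion
network classifies every session correctly (precision, recall and F1 all 1
for the depressed class). At the published full scale:

```r
count_parameters(fusion_network(network_spec()))   # L = 1700
#> ... per-layer table ...
#> Total trainable parameters: 5,907,283
```

A command-line interface over the same functions lives at
`inst/cli/gatefusion.R` (verbs `simulate`, `preprocess`, `train`,
`evaluate`, `fuse`, `report`).

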