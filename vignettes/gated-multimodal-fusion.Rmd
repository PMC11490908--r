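---
title: "Gated multimodal fusion for interview-based depression detection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gated multimodal fusion: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatefusion)
```

## The problem and the data shape

Clinical-interview corpora for depression screening (DAIC-WOZ being the
canonical, licensed example) pair each session with three streams: a
timestamped transcript with speaker labels, a framewise audio-feature table
(74 features — twelve MFCCs among other auditory cues — every 10 ms), and a
framewise video-feature table (388 features covering facial landmarks,
action units, gaze and pose). Labels are binary: depressed (59 of 189
sessions) or not (130 of 189). Sessions run 7 to 33 minutes.

gatefusion implements the full modelling pipeline over this shape: I/O and
validation for the CSV shell, a synthetic cohort generator, sentence-level
alignment, a gated fusion network with exact parameter accounting, classical
and convolutional and recurrent baselines, stacked late fusion, and a
precision/recall/F1 harness. The licensed corpus itself is neither required
nor touched.

## Sentence-level alignment

The three modalities live on incompatible clocks (utterances, 100 Hz frames,
30 Hz frames). The shared index is the *participant utterance*: each becomes
one time step, in transcript order; interviewer turns are dropped, because
the participant's speech is the clinical signal carrier.

- Frame slice: an utterance `[start, stop)` maps to 0-based frame indices
  `[floor(start/period), floor(stop/period))` — half-open, so adjacent
  utterances get disjoint slices. Windows beyond the table end are truncated
  with a warning; empty slices yield a zero step.
- Audio/video step: per-feature **mean** over the slice. Mean (rather than
  max or SD) is the aggregation most robust to i.i.d. frame noise; the
  choice is exposed as `agg` in `align_session()`.
- Text step: the mean of the utterance's 300-d token embeddings concatenated
  with the token count, giving 301 dimensions. The 301-width is read as the
  300-dimension embedding convention plus one lexical scalar; nothing in the
  source material decomposes it further, so this is recorded as an
  assumption.
- Sequences are zero-padded (or truncated, keeping the earliest steps) to a
  fixed L. The default L = 1700 follows the published layer table; a
  6000-length variant appears elsewhere in the same source and is available
  as a configuration override, not the default, because the layer table's
  parameter counts are the verifiable anchor.

Word-level alignment (for the word-gating variants) gives every token its
own step — the token's embedding plus a count of 1 — and repeats the parent
utterance's audio/video slice mean, since word-level forced alignment is not
available in this schema.

Alignment is label-independent by construction; a property test permutes
labels and checks that no tensor changes.

## The gating block

The published per-layer parameter counts pin down the gating layer's
structure. A standard highway layer of width d has `2·(d² + d)` trainable
scalars, which does **not** reproduce the published 262,552 (d = 74) or
1,620,288 (d = 388). The closed form `2·(d² + L·d)` — d×d gate and transform
weights plus *per-timestep* L×d biases — reproduces both exactly at
L = 1700. The block is therefore implemented as

```
g_t = sigmoid(x_t W_G + b_G[t]),  h_t = relu(x_t W_T + b_T[t]),
out_t = g_t ⊙ h_t + (1 − g_t) ⊙ x_t
```

This reconstruction is derived from the counts, not stated in prose
anywhere; it is the package's central reverse-engineering decision. Two
limits are property-tested: biases `b_G → −∞` close the gate and the block
is the identity (max |out − in| < 1e−6); `b_G → +∞` opens it and the block
is the transform path.

## The fusion network

Streams: video through three stacked gating blocks (388) then dense
388→200→74; audio through three gating blocks (74) then dense 74→74; text
dense 301→150→74 without gating. The three L×74 sequences are concatenated
**along the time axis** — the published fused shape (5100×74 = 3·1700 × 74)
forces time-axis concatenation but not the order; audio, video, text is
fixed as a configuration constant so runs are reproducible. An LSTM
(128 units, last state) and a single logistic unit close the network.
`count_parameters()` reports every layer from the actual arrays; the total
is 5,907,283.

Dense counts are `out·(in+1)`, the LSTM `4·u·(in+u+1)`; both are
property-tested at random sizes. Whether the three stacked gating blocks
share weights is unstated in the source; the counts list each block
separately, so they are independent.

### Numerical choices

- Initialization: variance-scaled uniform (Glorot) weights, zero biases,
  forget-gate bias 1 — all seeded. With all-zero input the untrained network
  outputs exactly probability 0.5 (zero biases and the gating algebra make
  every stream vanish), which is asserted in the tests.
- Optimizer: Adam with step size 1e−3, decay 0.9/0.999, epsilon 1e−8. The
  optimizer family is stated in the source; its hyperparameters are not, so
  the standard defaults are used.
- Loss: binary cross-entropy from logits (sigmoid folded into the loss for
  stability, with a 1e−12 floor inside the logarithms).
- Calls: probability ≥ 0.5 is positive; the tie goes to the positive
  (depressed) class.
- A non-finite loss aborts training with the epoch, batch and step size in
  the message.
- All gradients are hand-derived and checked against central finite
  differences (per layer and through the whole network) in the test suite.

### Reach of the last-state readout

Time-axis concatenation plus a last-state LSTM readout has a structural
consequence worth stating plainly: at initialization the forget gate sits
near sigmoid(1) ≈ 0.73, so state decays with a half-life of about two steps.
Class signal placed in the *audio* block — the first third of the fused
sequence — must survive the entire video and text blocks (2L steps) before
reaching the readout, and is numerically extinct there at initialization;
gradient descent gets no foothold. The desk-scale trainability oracle (40
sessions, L = 100, > 0.95 training accuracy within 30 epochs) therefore
places the strong signal in the **text** stream, the block adjacent to the
readout, and uses sessions with enough utterances to fill the L steps
(padding rows are zeros and only shorten the informative suffix further).
Short-sequence settings (L ≤ ~10 per stream) do not suffer from this and are
used for the audio-ablation recovery test. This is a property of the
published architecture, not of this implementation; with masking-free
padding the same limit applies at full scale.

## The synthetic cohort generator

The generator reproduces the corpus shell — not its content:

- `cohort_spec()`: 189 sessions, depressed fraction 59/189, durations
  uniform on [420 s, 1980 s], audio frames every 0.010 s, video at 30 Hz
  (the source never states the video rate; 30 Hz is the common standard and
  is exposed as a parameter), about 8 utterances per minute alternating
  interviewer/participant with participant speech covering roughly half the
  session.
- Features: frame value = class shift + session intercept + noise, i.e.
  `Normal(label·shift_j + u_j, σ²)` with `u_j ~ Normal(0, session_sd²)`.
  The session-level random intercept (default SD 0.3) is what keeps
  session-level classification from collapsing to triviality: utterance
  means average away frame noise, so without between-session variation any
  nonzero shift would be perfectly separable.
- Text: utterances are 5–15 tokens from a neutral base lexicon; participant
  utterances of depressed sessions contain a token from a fixed
  anhedonia/fatigue marker lexicon with probability `text_marker_rate`
  (default 0.35) versus `text_marker_base` (0.15) otherwise. This gives
  TF-IDF and embedding features a mechanical, tunable class signal.
- Default shifts: 0.15 SD on the first 12 audio features (the MFCC block)
  and 0.10 SD on 24 video features (the action-unit block). The source
  reports no effect sizes; these are one-time choices of moderate,
  field-plausible magnitude and are *not* calibrated to reproduce any
  published score.
- Determinism: one global seed derives a per-session stream (seed + session
  ordinal), so cohorts are byte-identical across runs and stable under
  partial materialization. The cohort index (labels, durations, seeds) is
  drawn first; frames are materialized on demand, which keeps full-scale
  cohorts (tens of gigabytes if fully expanded) cheap to index.

What the generator does **not** emulate: temporal autocorrelation within
frames, acoustic or visual realism, natural language, annotator noise, and
any cross-modality correlation beyond the shared label. Passing tests
therefore demonstrate that the pipeline's mechanics are correct and that
fusion recovers controllable signal — not that any model would reach a
particular score on the real corpus.

## Balancing, first-stage classifiers and stacking

The corpus's 7:3 imbalance is handled by minority upsampling: minority
entries are duplicated (sampling with replacement, seeded) until both
classes match the original majority count — (130, 59) → (130, 130).
Upsampling is applied to the *training split only, after splitting*; the
source does not state the order, and balancing before splitting would leak
duplicated sessions across the boundary.

Classical classifiers consume session-level summaries (the source does not
say what its SVM/RF consumed): TF-IDF plus word count, mean sentence length
and type-token ratio for text; per-feature mean and SD for audio (148) and
video (776). First-stage scores for stacking are produced by seeded 5-fold
cross-fitting — each session is scored by a model that never saw it — and
the second-stage SVM trains on those out-of-fold scores in a fixed modality
order. Degenerate columns (constant within a fit) are dropped per fit.
SVM scores are logistic-squashed decision values rather than Platt-scaled
probabilities, which keeps tiny desk-scale fits stable.

The six-layer CNN baselines read "six layers" as six weight-bearing layers:
three convolutions (2-D over the text grid as a one-channel image; 1-D along
time for audio/video), each followed by width-2 max pooling, then two
rectifier affine layers and the logistic output. Filter counts and kernel
sizes are unstated in the source; 32 filters, kernel 3, pooling 2 are the
recorded defaults.

## Evaluation conventions

Positive class = depressed throughout. Precision, recall, F1 and accuracy
follow the standard closed forms with zero conventions for empty
denominators (needed because desk-scale runs can produce empty prediction
classes); F1 = 0 when precision + recall = 0. Splits are stratified 80/20 by
session with a recorded seed — the source never states its split, so every
report row carries its own split description. Evaluating on training
sessions is a hard error unless explicitly allowed, in which case the row is
flagged. Chance level is referenced by a label-permutation null of F1; the
test suite checks "no better than chance" as a mean deviation within three
standard errors over seeds (with a 0.05 absolute floor so that a degenerate
zero-variance null cannot fail on rounding).

## Problem sizes used by the tests

The parameter-accounting checks run at the full published scale (L = 1700),
which needs no training. Behavioural tests use desk-scale cohorts chosen to
exercise every code path quickly: 12–40 sessions of 20–90 s, L between 6 and
100, 8–128 recurrent units, and 3–30 epochs; the trainability oracle uses
the 40-session, L = 100 configuration described above. These sizes are the
package's own testing choices and are stated here so that results are
interpretable.

## Known limitations

- The pretrained-transformer text pipeline of the original system is out of
  scope; a pluggable sentence-encoder interface (any utterance → fixed
  vector map, defaulting to a seeded random embedding table) stands in its
  place.
- The last-state readout limits how far back in the fused sequence usable
  signal can sit (see above); pooling readouts would remove the limit but
  would not match the published layer table.
- The generator's independence assumptions (no temporal structure, no
  cross-modality correlation beyond the label) make synthetic performance
  numbers incomparable to published corpus scores, by design.
- Determinism guarantees assume single-threaded BLAS; multi-threaded
  reductions may differ in the last bits.
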