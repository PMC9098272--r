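---
title: "Decoding motor-imagery EEG with an attention-based DSC-ConvLSTM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor-imagery EEG with an attention-based DSC-ConvLSTM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The decoding problem

Motor imagery elicits event-related desynchronization (ERD): when a subject
imagines moving a hand, the ongoing mu (8--12 Hz) and beta (18--26 Hz)
rhythms over the contralateral sensorimotor cortex lose band power relative
to the pre-cue baseline. A four-class motor-imagery brain-computer interface
(left hand / right hand / feet / tongue) must recover, from a few hundred
cue-locked multichannel EEG trials, which spatial-spectral pattern of
desynchronization each trial carries. `midecoder` implements a compact deep
decoder for this problem and everything needed to exercise it end to end:
cropped training, a depthwise-separable convolutional feature extractor, a
modified bidirectional ConvLSTM with temporal attention, a 4-fold
cross-validation harness, and a synthetic ERD/ERS generator so the whole
pipeline is testable without any external download.

## Sliding-window cropped training

Each trial spans -0.5 s to 4 s around the cue (1,125 samples at 250 Hz).
Rather than feeding whole trials to the network, 2-s windows are slid across
each trial with start times from -0.5 s to 2 s. At stride 1 sample that
yields exactly 625 crops per trial (`count_windows(crop_spec())`), each
treated as an independent training example with the trial's label. At
evaluation time the decoder's softmax outputs over a trial's windows are
averaged and the trial is decoded as the argmax of the mean.

Two readings of the training loss are defensible: the mean over windows of
the per-window cross-entropy, or the cross-entropy of the averaged
probability. Both are implemented (`loss_mode` in `train_config()`);
`per_window` is the default because it treats each crop as an example (the
standard cropped-training construction) while probability averaging remains
the evaluation rule either way. Trials are always split into
train/validation/test *before* cropping, so windows from one trial never
straddle a fold boundary.

## The feature extractor

The backbone is a four-block depthwise-separable convolution stack
(`backbone_config()`):

* **Block 1** factorizes the first convolution into a temporal filter bank
  (F1 kernels of 64 samples, learning band-pass-like filters) and a
  depthwise spatial filter spanning the full electrode axis (kernel
  `(C, 1)`, D filters per temporal map), each followed by batch norm
  (eps 0.001, momentum 0.01), then ELU, max-pool `(1, 3)` and dropout
  (p = 0.25 within subjects; 0.5 is the published cross-subject setting).
  After the spatial filter the electrode axis has extent 1.
* **Blocks 2--4** are separable convolutions: a depthwise temporal kernel of
  16 samples per map, a pointwise (1x1) cross-map combination, batch norm,
  ELU, pooling by 3 and dropout. Blocks 2--3 max-pool; block 4 mean-pools,
  preserving aggregate band-power information in the deepest features.

Temporal kernels use same-length zero padding (32 left / 31 right for the
64-sample kernel), so the time axis shrinks only at the pools:
`T' -> T'//3 -> T'//9 -> T'//27 -> T'//81`; a 500-sample window leaves 6
time steps of `F4` feature maps. Convolutions carry no bias terms: each
convolution is immediately followed by an affine batch norm, which absorbs
any bias exactly, and dropping them keeps the parameter calibration below
well-posed.

## The recurrent head

The 6-step feature sequence feeds a modified ConvLSTM run in both
directions. Inputs and the previous hidden state are globally mean-pooled
over any residual spatial extent; the three gates are ordinary dense
sigmoids of the pooled vectors; only the candidate path is convolutional:

    f_t = sigmoid(W_xf X~_t + W_hf H~_{t-1} + b_f)
    i_t = sigmoid(W_xi X~_t + W_hi H~_{t-1} + b_i)
    C~_t = f_t . C_{t-1} + i_t . tanh(w_xc * X~_t + w_hc * H~_{t-1} + b_c)
    o_t = sigmoid(W_xo X~_t + W_ho H~_{t-1} + b_o)
    H_t = o_t . tanh(C~_t)

where `*` is a 1-D convolution along the feature axis with a shared
odd-length kernel (default 3, symmetric zero padding). Three design points
deserve a note because the construction leaves them genuinely open:

* **Where the convolution acts.** After global mean pooling the per-map
  spatial extent is 1, so the only axis a convolution can traverse is the
  feature-map axis. This keeps the claim "only the input-to-state
  transformation is convolutional" literal while the gates stay dense.
* **The cell memory.** The candidate expression already blends the previous
  memory through the forget gate, and the output equation consumes it
  directly, so `C~_t` *is* the next cell memory; there is no separate
  `C_t` update.
* **Hidden width.** Because `w_xc * X~_t` (length = number of feature maps)
  and `w_hc * H~_{t-1}` (length = hidden width) are summed elementwise, the
  hidden width must equal the feature-map count `D*F4`. The hidden width is
  therefore not a free hyperparameter here; it is fixed by the backbone.

The forward and backward hidden sequences are concatenated per time step
(width `2 * hidden`), and attention pooling collapses time: keys
`Z_t = tanh(W_w H_t + b_w)`, weights `a_t = softmax_t(Z_t' Z_w)`, output
`y = sum_t a_t H_t`. The attention weights are strictly positive and sum to
one, so `y` lies in the convex hull of the hidden states. Attention is
applied to the recurrent output sequence -- the operational definition given
by the equations -- rather than to the raw input. A pointwise (1x1)
convolutional classification layer with bias maps `y` to class logits,
followed by softmax.

## Calibrating the unprinted widths

The filter counts F1--F4 and the recurrent hidden width are not published;
the one hard anchor is the model's total of 17,972 trainable parameters.
`calibrate_architecture()` enumerates small filter ladders (powers of two
and near neighbors up to 64) and candidate kernels, solves the parameter
equation for the attention key dimension (which enters linearly), and keeps
exact solutions. Forty-seven configurations hit the target exactly; the
package prefers monotone power-of-two ladders with candidate kernel 3, then
the widest ladder (most feature capacity), which selects filters 8/16/32/32,
hidden width 32, attention key dimension 26. The preference rule is a
convention, chosen once and fixed; every exact solution remains available
from the search table.
One published detail is knowingly overridden: the table prints a block-1
padding of `(0, F1*2)`, which cannot preserve length for a 64-sample kernel,
while the same table's output column asserts the length is preserved.
Same-length symmetric padding honors the output column.

## Training protocol

Adam minimizes the cropped cross-entropy; 4-fold cross-validation assigns
each class-stratified quarter of the trials to two training folds, one
validation fold and one test fold, rotating so every trial is tested exactly
once. Validation trial accuracy (window probabilities averaged per trial)
drives early stopping, and the best-validation weights are restored.
Learning rate, batch size, epoch budget and patience are unpublished
tunables; the package defaults are lr 1e-3, batch 64, 100 epochs, patience
15, all exposed in `train_config()`. Stratified splitting is itself an
assumption (the protocol's published description does not say how folds are
balanced); it prevents degenerate folds on small datasets.

Weight initialization is seeded and deliberate: the block-1 temporal
kernels start as a Gabor filter bank -- windowed cosines with center
frequencies evenly laddered across 2 to 7 cycles per kernel (7.8--27 Hz for
the default 64-sample kernel at 250 Hz, spanning mu and beta) and random
phases, normalized to the scale of a fan-in uniform draw. Block 1 is
designed to learn band-pass filters; starting from band-pass structure
rather than white noise removes a long silent plateau at the start of
training while leaving every coefficient free to adapt. Recurrent matrices
are orthogonal, all other weights fan-in-scaled uniform, biases and initial
states zero.

Reproducibility is strict: the generator, the fold split, weight
initialization, minibatch shuffling and dropout masks all draw from seeded
RNG streams, so identical configurations reproduce identical loss series
bit for bit.

## The synthetic data generator

`generate_dataset(synthetic_spec(...))` emulates exactly the physiology the
decoder exploits. Every channel carries each rhythm band as band-limited
Gaussian noise (random phase, default SD 5 uV) over 1/f background noise
(default exponent 1.0, SD 2 uV). For a trial of class k, the class's band on
the class's channel subset is multiplicatively attenuated during the
post-cue period: the envelope scales by `sqrt(1 - erd_depth)` so that band
*power* drops by the factor `(1 - erd_depth)`, which is what a Welch
band-power oracle measures (`erd_attenuation()`). Class topographies default
to a lateralized block scheme mirroring somatotopy (left hand ->
right-hemisphere block, right hand -> left, feet -> central), so the spatial
filter has genuine structure to learn. `erd_depth = 0` produces data with no
class information at all -- the chance-level control.

What the generator does **not** emulate: volume conduction and realistic
electrode covariance, non-stationarity across a session, artifacts
(a rudimentary EOG-blip flag exists, default off), and subject-to-subject
variability. Passing tests on synthetic data therefore demonstrate that the
implementation learns class-conditioned band-power structure end to end --
not that it attains any particular accuracy on real recordings.

The published ERD magnitude is not quantified in the source material; the
generator's `erd_depth` and noise levels are calibration choices of this
package, fixed once (defaults 0.5 / rhythm 5 uV / noise 2 uV) and stated
here rather than tuned against outcomes.

## Desk-scale problem sizes

The test suite exercises the full protocol at sizes a single CPU handles in
minutes, chosen as the package's own desk-scale conditions: 160 trials of
22-channel synthetic data at `erd_depth` 0.8, crop stride 50 (13 windows per
trial), learning rate 3e-3, batch 64, at most 16 epochs with patience 8.
The learning rate sits above the 1e-3 default because the published
batch-norm momentum (0.01) makes the inference-time statistics converge
slowly; at desk scale the higher rate lets features -- and with them the
running statistics -- settle within the epoch budget. The Gabor filter-bank
initialization of the temporal kernels (see below) serves the same end: it
removes the many epochs white-noise filters otherwise spend before
oscillatory structure emerges. The chance-level
control trains the same pipeline on `erd_depth = 0` data for a short budget,
since there is nothing to learn. Unit tests run the same code paths on
miniature configurations (3--4 channels, 100 Hz, filter counts 2--3), and
the hand-written backward pass is verified against central finite
differences on every parameter group.

## Numerical choices and degenerate inputs

* Batch-norm uses biased (1/n) variance in both the normalization and the
  running estimate, eps 1e-3, momentum 0.01 (torch-style update
  `running <- 0.99 running + 0.01 batch`).
* Max-pool ties take the earliest sample; pooling drops trailing samples
  beyond `3 * floor(T/3)`; trial decoding breaks probability ties toward
  the lower class index -- all deterministic conventions.
* Softmax and cross-entropy subtract the row maximum and clamp propensities
  at 1e-12 before the log.
* Dropout is inverted (scaling by `1/(1-p)` at train time), so evaluation
  needs no rescaling.
* Window start-sample rounding is round-half-away-from-zero; with the
  default geometry the offset is exactly 0 samples.
* Degenerate geometries (windows exceeding the trial, time axes too short
  for a kernel or pool, empty prediction sets, empty sequences) raise
  classed errors naming the failing stage rather than producing silent
  misalignment.

## Known limitations

* GDF recordings are not parsed; EDF (with a plain-text event sidecar) is
  the supported container, and the internal store is RDS.
* The published headline accuracies on the two public benchmark datasets
  are out of this package's test scope: they require the external downloads
  and full-scale training. The package reproduces the *structural* published
  quantities (window counts, shape chain, parameter total) exactly and
  validates the learning dynamics on synthetic data.
* The rejected design variants discussed alongside the architecture
  (convolutions inside gates, attention inside gates) are not implemented;
  the ablation switch covers only the recurrent/attention head as a whole.
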