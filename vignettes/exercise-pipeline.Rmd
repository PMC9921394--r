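---
title: "Recognizing and counting strength exercises from chest and hand accelerometers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing and counting strength exercises from chest and hand accelerometers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(exertrack)
```

## The problem

A person works through a training session of dips, pull-ups and squats,
pausing between series, while wearing two accelerometers (chest and hand)
sampled at 30 Hz. From the six streaming acceleration channels we want two
things: the **scenario** — the ordered sequence of exercises performed —
and the **repetition count** of every series. Together they let a training
application check a session against its plan.

`exertrack` implements this as two cooperating modules:

* an **activity recognition module**: a compact convolutional classifier
  slid over the stream one sample at a time, followed by a post-processing
  block that turns noisy per-sample class probabilities into clean labeled
  segments;
* a **repetition counting module**: per recognized segment, a zero-phase
  low-pass filter on the channels known to carry the repetition movement,
  then peak counting under spacing and prominence constraints.

Because the original study data are not publicly deposited, the package
also contains a first-class synthetic generator that reproduces the
statistical structure of the study corpus, so the full pipeline can be
trained, exercised and scored end to end from a seed.

## The synthetic corpus

The generator's defaults encode the published corpus statistics:

* **Scenarios.** 15 scenarios with protocol counts summing to 78
  (`scenario_table()`); the dominant one (pull-ups, dips, squats) accounts
  for 28 of 78 protocols. Scenarios are drawn proportional to these counts.
* **Repetitions.** Per-activity repetition counts and single-repetition
  durations are drawn uniformly within the published ranges
  (`activity_stats_table()`): e.g. squats 2–15 repetitions of 33–130
  samples each.
* **Occurrences.** The published corpus also reports the range of whole
  occurrence durations (e.g. every pull-up series lasted 91–765 samples),
  and the post-processing thresholds were derived from those statistics.
  The generator therefore rejection-samples (count, durations) jointly
  until the occurrence duration falls inside the published range.
  Without this constraint, uniform draws can produce a one-repetition
  pull-up series shorter than the 90-sample peak-elimination threshold —
  a series the real corpus never contained, and one the recognizer is by
  design unable to keep.
* **Breaks.** Uniform within 63–1844 samples, bracketing every activity
  (leading and trailing breaks included), so segment-boundary edge cases
  are always exercised. The 63-sample minimum is load-bearing: it is what
  makes a 50-sample window unable to span two different exercises.

Each repetition is rendered as one half-cosine excursion-and-return bump
spanning its duration — the simplest waveform that is visually similar to
the published raw traces, has exactly one extremum per repetition
(analytically countable, which the tests exploit), and concentrates its
energy at the repetition frequency. The bump is placed, with amplitude
3 m/s² by default, on the activity's **informative channels** (dips:
chest z, hand x, hand z; pull-ups: chest y, chest z, hand z; squats:
chest z — the channel sets identified in the study and consumed by the
repetition counter), and with amplitude 1 m/s² on the remaining channels.
All channels ride on a gravity baseline (9.81 m/s² on the z channels)
with Gaussian noise (sd 0.3 m/s²); breaks additionally contain sparse
low-amplitude transients (0.05 events/s, up to 1 m/s²) emulating
incidental movement. These four numbers are the generator's assumptions,
not published facts; they were fixed once at values giving a realistic
signal-to-noise ratio for a body-worn MEMS accelerometer and are all
overridable in `generator_config()`.

What the generator does **not** emulate: person-specific movement
signatures, tempo drift within a series, sensor orientation changes,
asymmetric or multi-phase repetition waveforms, and non-exercise
activities other than quiet breaks. Passing tests on this corpus
demonstrate that the pipeline's machinery is correct and well-calibrated
for signals with the study's timing structure; they do not certify
performance on real recordings.

## Windowing and labels

Training data are 50-sample x 6-channel windows cut from full recordings,
under two regimes: non-overlapping (step 50) and half-overlapping
(step 25). Each window carries a **soft label**: the fraction of its
samples belonging to each of the four classes (break, dip, pull-up,
squat). Windows interior to a segment get one-hot targets; windows
spanning a boundary get fractional ones.

A soft label collapses to a **hard label** with exercise precedence:
since breaks separate all activities and the shortest break (63 samples)
exceeds the window, a heterogeneous window can only mix one exercise with
break, and it is treated as that exercise even when break holds the
majority. For probabilistic classifier outputs, "registered" exercise
mass is required to exceed one sample's worth (1/50) — below that, a
softmax's inevitable non-zero leakage would otherwise make a confident
break prediction impossible. Exercise ties break by fixed class order,
for determinism.

Datasets are split 70:15:15 into train/validation/test uniformly at
random at window level (the simplest reading of the study design;
`split_dataset()` is seeded and reproducible). Normalized variants
z-score each channel with statistics fitted on the training split only.

## The classifier

One convolution layer (5 filters, kernel 7 x 1 — seven samples along
time, one along channels, no padding), ReLU, 2 x 1 max pooling along
time, flatten, dense softmax over 4 classes:
conv (44, 6, 5) → pool (22, 6, 5) → flatten 660 → dense 4, i.e.
5·(7+1) + 4·(660+1) = **2684 trainable parameters**, asserted at build
time. The kernel interpretation is pinned by the published shapes
(44 = 50 − 7 + 1 and an unchanged channel axis); pooling 2 x 1 follows
from 44 → 22.

No deep-learning framework is involved: at 2684 parameters the network
is small enough that construction, the forward pass, backpropagation and
Adam fit comfortably in vectorized base R (an im2col matrix per
minibatch plus BLAS matrix products). The forward pass is verified in
the test suite against an independent loop-written oracle to 1e-5.

Training choices (unstated in the study, fixed here in
`model_config()`): categorical cross-entropy against the soft targets;
Adam with learning rate 1e-3; minibatch 128; at most 200 epochs;
early stopping on validation loss with patience 10 and restoration of
the best-validation weights. Glorot-uniform initialization, seeded — a
training run is reproducible from its seed.

Streaming inference slides the window one sample at a time. The
convolution is computed once over the whole recording and shared between
overlapping windows, so an N-sample stream costs one (N−6) x 6 x 5
convolution plus one matrix product instead of N−49 independent forward
passes; the result is bit-identical to per-window prediction (tested).
The prediction of the window starting at sample *t* is assigned to
sample *t*+49 — the most recent sample the window has seen — which is
the only alignment available to a live system. The resulting
half-window latency is what produces the small time shifts of recognized
segments against the protocol, and the post-processing tolerances absorb
it.

## The post-processing block

Raw per-sample probabilities are too jittery to read a scenario from:
short misclassification bursts create spurious activity peaks, and short
dropouts punch gaps into genuine activities. Each class stream is
therefore processed independently:

1. **Moving average** over a forward-looking window of w = 50 samples
   (the value at *i* averages samples *i* … *i*+w−1, truncated at the end
   of the stream so the output keeps the input length). The forward
   window partially cancels the causal alignment latency above.
2. **Binarization** at 0.5 (the threshold is a configuration choice; ≥
   maps to 1).
3. **Peak elimination**: maximal runs of 1s of length ≤ δ₁ = 90 are set
   to 0. The comparison is strict — a run must *exceed* the threshold to
   survive — because the shortest genuine occurrence in the corpus is 91
   samples.
4. **Gap filling**: maximal runs of 0s of length ≤ δ₀ = 60 are set to 1;
   the shortest genuine break is 63 samples. Gaps are filled after peaks
   are removed so that filling cannot resurrect fragments of a deleted
   spurious peak.

Both run-length stages are idempotent and are tested against a
brute-force run-enumeration oracle on 10,000 random binary strings.

The four cleaned streams are then collapsed into one labeled
segmentation. Per sample: exactly one active exercise stream wins; no
active stream means break; where independently cleaned streams overlap,
the exercise that has been continuously active the longest up to that
sample wins, with ties resolved by class order. Maximal runs of the
winner sequence become segments, and the scenario is the sequence of
non-break segment labels.

## The repetition counter

For each recognized exercise segment the counter reads only that
activity's informative channels. Each channel slice is filtered with a
zero-phase (forward–backward) order-2 Butterworth low-pass whose
normalized cutoff is activity-specific (dips Wn = 0.05, pull-ups 0.04,
squats 0.06, as fractions of the 15 Hz Nyquist — i.e. cutoffs of
0.75/0.6/0.9 Hz, just above each activity's fastest plausible repetition
rate). Zero-phase filtering keeps peaks in place, which matters because
the counter consumes segments that are already slightly time-shifted;
the series is extended by odd reflection before filtering to suppress
edge transients, since plain forward–backward filtering with zero
initial state would otherwise ring at the segment ends.

Peaks are then counted under two constraints: a minimum spacing per
activity (40/50/30 samples — just under the fastest observed single
repetition; enforced by greedy highest-first suppression) and a
topographic prominence of at least 10% of the filtered segment's range.
The prominence floor is this package's addition: filtering alone leaves
low-amplitude local maxima on nearly flat channels, and a relative floor
discards them without introducing an absolute scale (the counter stays
invariant to offset and positive rescaling, which is tested). Setting
`prominence_frac = 0` restores pure distance-constrained counting.

Because the excursion direction of a repetition is not knowable in
general (a pull-up pulls the chest up, a dip drops it), each channel is
counted **two-sided**: the count is max(peaks of x, peaks of −x). For a
train of n single-sided bumps the excursion side yields n and the
opposite side at most n−1 interior troughs, so the rule is sign-agnostic
without overcounting. (A median-excursion heuristic that picks one side
was evaluated and rejected: a segment that is wall-to-wall repetition
bumps is nearly symmetric about its median, making the choice a coin
flip that undercounts by one when it lands on the trough side. The
heuristic remains available as `polarity = "median"`.)

The per-channel counts are averaged and rounded half-up (mean 5.5 → 6);
rounding direction is a convention the study does not state.

## Evaluation

* **Window accuracy**: fraction of held-out windows whose hard label
  matches the truth's hard label.
* **Per-sample activity recall**: per class, the fraction of
  ground-truth samples of that class labeled identically by the
  predicted segmentation; classes absent from the truth are omitted
  rather than scored 1 (0/0 is reported as absent). The total is the
  fraction over all samples. This is deliberately a different quantity
  from window accuracy, and both are reported separately.
* **Scenario accuracy**: fraction of protocols whose extracted scenario
  equals the truth exactly, order and multiplicity included.
* **Repetition accuracy**: predicted segments are paired to truth
  exercise segments by maximal same-label overlap (an unmatched truth
  segment is charged a predicted count of 0); accuracy is the fraction of
  segments within a tolerance of 0, 1 or 2 repetitions, per activity and
  overall, each segment weighing equally. The miscount rate is
  Σ|predicted − true| / Σtrue.

`run_benchmark()` wires everything together: it trains a classifier on
one generated corpus, evaluates on a disjoint one (the evaluation seed
is the run seed plus a fixed offset), and returns all of the above. The
default problem sizes — 30 training protocols (≈7,000 half-overlapping
windows, matching the scale of the study's window corpus) and 100
evaluation protocols — were chosen to mirror the study's corpus size
while keeping a full benchmark run in the minutes range on one CPU.

## Degenerate inputs and numerical conventions

* Segments are 0-based, half-open `[start, end)`; protocols must tile
  the recording exactly, with breaks separating all exercises —
  violations are errors, not warnings.
* Resampling never extrapolates: the uniform grid is confined to the
  observed time support, and stream synchronization uses the
  intersection of supports (empty intersection is an error).
* A constant series has no peaks; prominence is computed against the
  higher of the two separating minima, as in topographic usage.
* The moving average of a constant series is that constant, for any
  window; `w = 1` is the identity.
* Standard deviations in the normalizer are floored at 1e-8, so constant
  channels z-score to 0 rather than NaN.
* Softmax is computed with row-max subtraction; cross-entropy clamps
  probabilities at 1e-12. A non-finite loss aborts training with an
  error rather than returning a broken model.

## Known limitations

* The classifier variants trained on normalized data (C2/C4) are
  supported but the deployed default is the overlapping-window raw-data
  variant (C3), mirroring the study's selection; raw-data training makes
  the classifier scale-dependent, which is harmless here because
  training and inference share the generator's scale, but real
  deployments should prefer the normalized variants across devices.
* The post-processing block operates on the recorded stream in batch, as
  in the study's evaluation; a bounded-latency online variant is out of
  scope.
* Posture or movement-quality assessment is explicitly not attempted —
  the system checks *what* was done and *how many times*, not *how
  well*.
* Generator realism limits transfer: see the synthetic-corpus section.
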