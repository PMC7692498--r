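---
title: "Validating QRS detections with a convolutional beat classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating QRS detections with a convolutional beat classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

False positives are the expensive failure mode of heartbeat segmentation: a
QRS detector that fires on noise erodes trust in downstream monitoring and
alarm systems. `qrsvalid` implements a two-stage design that attacks exactly
this failure mode. A classic Pan-Tompkins adaptive-threshold detector
proposes candidate R-peaks; a small one-dimensional convolutional network,
trained on beat morphology, then acts as a second judge and accepts or
rejects each candidate. Because acceptance is a *subset* operation, the
validator can only remove detections: positive predictivity (+P) can rise,
sensitivity (Se) can only fall, and the package asserts these subset
relations on every run. The practical question the package answers is
whether the +P gain is large while the Se cost is small.

## The pipeline

Six steps, each its own module:

1. **Database split** — train/test partitions are built per *subject*, never
   per record (`make_subject_split()`), and `run_experiment()` refuses any
   configuration in which a subject appears on both sides.
2. **Pre-processing** — every classifier input is a fixed 833 ms window:
   300 samples at 360 Hz. Records at other rates are windowed at their
   native rate (833 samples at 1000 Hz) and each window is resampled to 300
   samples with piecewise-cubic spline interpolation
   (`resample_to_length()`), which preserves endpoints and reproduces
   constants and straight lines exactly. We deliberately resample windows,
   not whole records, so annotation indices never shift.
3. **Training-set construction** — see *Augmentation* below; applied to
   training partitions only.
4. **R-peak detection** — `pt_detect()`, the Pan-Tompkins cascade.
5. **Validation** — `validate_detections()` feeds the window centred on each
   candidate through the CNN and keeps candidates with beat probability at
   or above 0.5 (configurable).
6. **Evaluation** — tolerance matching (`match_detections()`) and pooled
   Se / +P / F-score (`compute_metrics()`), reported for raw and validated
   detections side by side.

## Augmentation

Each eligible annotated beat yields exactly eleven beat-labelled windows:
the centred window; copies shifted so the R-peak sits ±5, ±10 and ±15
samples off centre; P-wave- and T-wave-attenuated copies (the 375 ms before
or after the R-peak scaled by 0.70); and 20% / 40% globally attenuated
copies. "Attenuated by 30%" is implemented as multiplication by 0.70 —
amplitude units are arbitrary, so only multiplicative scaling is unit-free.
The attenuated variants derive from the *centred* window, keeping the
per-beat count at exactly 11. The wave attenuations exist to make the
classifier robust to the real-world failure mode of high-frequency noise
distorting the low-amplitude P and T waves, while the shifts define the
matching tolerance used at evaluation time (±15 samples at 360 Hz,
rescaled as `round(15/360 * fs)` at other rates).

Negative (non-beat) windows are harvested between consecutive beats: starts
advance with a 5-sample stride from 50 samples after the first R-peak while
the window still ends at least 50 samples before the second. We require the
*whole window* to fit inside the margin-trimmed interval (not merely its
centre), which guarantees no R-peak comes near the window. A beat whose
window would cross a record boundary is skipped, never padded: padding
would fabricate morphology for the classifier to learn.

## The detector

`pt_detect()` follows the classic cascade: band-pass (5–15 Hz), five-point
derivative, squaring, and 150 ms moving-window integration. The band-pass
is a zero-phase Butterworth (order 3, applied forward–backward), so the
filtered signal stays aligned with the input and peak indices need no delay
correction. Candidate peaks of the integrated signal are classified against
dual adaptive thresholds (THR2 = THR1/2 always; signal/noise running
estimates with 0.125 update weight; THR1 = noise + 0.25·(signal − noise)),
initialised from the first 2 s of signal. Three classic refinements are
implemented: the 200 ms refractory veto, T-wave discrimination (a candidate
200–360 ms after a beat whose maximal slope is under half the previous
beat's is noise), and searchback (when no beat appears within 166% of the
running mean RR, the largest skipped candidate above THR2 is accepted with
halved update weight). Each accepted beat is localised as the magnitude
argmax of the band-passed signal in the window preceding the integrated
peak. Every threshold is derived from the signal itself, so detection
indices are invariant under positive rescaling — a property the tests
assert directly.

## The classifier

Four convolution stages (kernels 49, 25, 9, 9; stride 1; no padding), each
followed by width-2/stride-2 max pooling, shrink a 300-sample input through
temporal lengths 252/126, 102/51, 43/21 and 13/6; two fully-connected
hidden layers and dropout precede a two-neuron softmax head. Channel counts
(32, 32, 64, 64), dense widths (512, 128), ReLU activations and the 0.5
dropout rate are package defaults — all configurable via `cnn_spec()` —
chosen to keep CPU training in the minutes range; the kernel/pooling
geometry is the fixed part of the design. Training uses plain SGD with
momentum 0.9 and cross-entropy loss for 30 epochs under a staged learning
rate (0.01 for epochs 1–3, 0.005 for 4–10, 0.001 for 11–20, 0.0001 for
21–30); 30% of the segments, stratified within each source record, form a
within-training validation partition. We split by segment (not by time
within a record): adjacent augmented windows of one beat may land on both
sides, which is acceptable here because this partition only steers
optimisation monitoring, never the reported test metrics — those come from
subject-disjoint records. Inputs are raw amplitudes with no filtering or
per-segment normalisation; the classifier judges shape as acquired. No
class re-weighting is applied to the roughly 2:1 positive:negative
imbalance the augmentation produces.

The network is implemented directly on BLAS matrix products (im2col), with
backpropagation verified against numerical differentiation in the test
suite. With a fixed seed, initialisation, the train/validation split,
shuffling and dropout are all reproducible, so two runs produce identical
histories.

## What the synthetic generator emulates — and what it does not

`generate_record()` models a beat as five Gaussians (P, Q, R, S, T) with
textbook amplitude/offset/width proportions, places beats quasi-periodically
(i.i.d. uniform RR jitter — the simplest bounded model, which keeps the
refractory assumption valid), and adds the standard noise taxonomy:
baseline wander (0.3 Hz sinusoid), powerline (50 Hz sinusoid) and
band-limited high-frequency noise (white noise high-passed above 25 Hz) —
the last being the component that corrupts P/T morphology. Annotations are
the exact template centres, and the noise-free R-peak is always the local
maximum at the annotation, a property the tests check.

Real ECG differs in ways the generator does not attempt: ectopic and
arrhythmic morphologies, electrode motion artefacts, QRS axis inversion,
heart-rate drift and beat-to-beat morphology variability. Passing the
synthetic suites therefore demonstrates that the pipeline's machinery is
correct and that the validator can learn and apply a morphology criterion —
not that the specific headline numbers would transfer to any particular
clinical database.

A generator-side constraint worth knowing: the error check for overlapping
beats guards the QRS core (Q/R/S extent) only. Adjacent beats' P and T
waves are allowed to overlap at short RR intervals, as they do
physiologically; merged QRS complexes, which would invalidate the
ground-truth annotation, are rejected with an error.

## The built-in end-to-end experiment

`synthetic_experiment()` is the package's desk-scale stand-in for a full
two-database study. Twenty training records and ten held-out test records
(15 beats each, 360 Hz) are generated with baseline wander (10% of R),
high-frequency noise (5%) and powerline interference (2%). The mean RR is
1.25 s with 0.05 s jitter — a slow-normal rhythm chosen once so that
between-beat negative windows exist at all: a 300-sample window plus two
50-sample margins requires RR ≥ 1.11 s at 360 Hz. The validator (default
architecture) trains for 10 epochs — the loss curve is flat well before
that on this task — on roughly 6,400 augmented segments. Test detections
come from `pt_detect()` and are then contaminated with 10% injected false
positives placed at least 0.2 s from every true beat
(`corrupt_detections()`), emulating a faultier third-party detector. The
report compares raw and validated detections; the expected outcome, which
the acceptance suite asserts, is a +P gain of several points against an Se
loss of at most a few points.

## Numerical and degenerate-input choices

* Indices are 0-based everywhere; windows are half-open `[start, start+L)`.
* Matching is greedy one-to-one by increasing distance, ties broken by
  earlier detection then earlier truth index — the standard beat-scoring
  convention; totals are tie-order invariant.
* `compute_metrics()` returns `NA` on zero denominators rather than
  erroring; percentages and the F-score are exact ratios, rounded only for
  display.
* All-zero records produce zero detections (thresholds are strict
  inequalities against signal-derived quantities, so nothing crosses).
* Detections whose validation window does not fit inside the record are
  rejected by the validator (the model cannot assess them) and count as the
  detector's false positives if unmatched.
* Seeds: every stochastic step (record generation, corruption, weight
  initialisation, splits, shuffling, dropout) flows from an explicit seed;
  child seeds are derived arithmetically and kept inside the 32-bit range.

## Known limitations

The detector implements the regular-rhythm configuration only; the
arrhythmia-mode threshold halving of the original algorithm is out of
scope, as is multi-lead fusion. WFDB support is read-only (formats 212 and
16). The CNN is a CPU implementation tuned for small studies — it is not a
framework, and very large training sets will be slow. The headline
percentages produced by the synthetic experiment characterise the synthetic
study conditions above; transferring them to clinical data requires the
corresponding databases and annotations.
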