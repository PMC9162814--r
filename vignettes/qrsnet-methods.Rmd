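---
title: "Methods: residual-CNN QRS detection and HRV-based intensity classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residual-CNN QRS detection and HRV-based intensity classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(qrsnet)
```

This vignette is the package's own account of its models, the parameters
that matter, and the design decisions taken where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Exercise monitoring from a wearable single-channel ECG reduces to three
coupled tasks: find the R peaks in a noisy voltage series, summarise the
resulting RR intervals as heart-rate-variability (HRV) features per epoch,
and map those features to an exercise-intensity level that can be compared
against an accelerometer-derived MET (metabolic equivalent of task) ground
truth. `qrsnet` implements each stage and, crucially, a synthetic-data
generator with exact ground truth so every stage is testable offline.

## Synthetic ECG generator

Each beat is the sum of five Gaussian bumps for the P, Q, R, S and T waves.
Defaults: offsets (−0.2, −0.05, 0, +0.05, +0.3) s relative to the R peak,
amplitudes (0.15, −0.1, 1.0, −0.25, 0.35) mV, widths (25, 10, 12, 12, 40) ms.
This is a standard minimal phantom: it reproduces the morphological facts the
detector relies on (a sharp dominant R deflection flanked by smaller waves at
fixed latencies) and nothing more. RR intervals are drawn as
`60 / mean_hr_bpm` seconds plus zero-mean Gaussian jitter whose standard
deviation is the configured `hr_sd_bpm` mapped through the local
linearisation `d(RR)/d(HR) = −60/HR²`; intervals are truncated below at
0.25 s so beats stay physiologically separated. The default sampling rate is
360 Hz, matching the MIT-BIH arrhythmia database, so window sizes transfer
unchanged.

Noise model, with each component's band chosen to match the classical
contaminant it emulates:

* **EMG**: white noise band-limited to 40 Hz–Nyquist by FFT masking, scaled
  to unit standard deviation before multiplication by its amplitude.
  Surface-EMG energy extends to several kHz; at 360 Hz only the portion
  below 180 Hz is representable, so the band is [40, 180] Hz by
  construction.
* **Powerline**: a pure 50 or 60 Hz sinusoid.
* **Baseline wander**: a slow sinusoid, default 0.3 Hz, constrained to
  [0.05, 2.0] Hz.

What the generator does **not** emulate: arrhythmic morphologies, ectopic
beats, electrode-motion transients, respiration-coupled amplitude
modulation, multi-lead geometry, or powerline harmonics. Tests passing on
synthetic data therefore demonstrate implementation correctness and
parameter recovery under the stated conditions — not clinical performance on
pathological ECG. The optional MIT-BIH harness (`run_mitbih_benchmark`)
exists for exactly that gap; it requires a local copy of the database.

For intensity experiments, `generate_intensity_sessions()` emulates a
MET logger worn alongside the patch: epoch METs are drawn uniformly within
each class range (low [1, 3], medium (3, 6), high [6, 10]) and heart rate
follows the linear model `HR = rest_hr + slope · MET` (defaults 60 bpm +
10 bpm/MET, i.e. class-mean HR of roughly 80/105/140 bpm — comfortably more
than the 15 bpm class separation the recovery experiments assume). A
non-positive slope is rejected because labels would be unrecoverable from
heart rate.

## Preprocessing

Three filters, one per contaminant, all zero-phase so peak positions never
shift (the detector's matching tolerance is ±75 ms; a causal filter's group
delay would eat a large share of it):

* **EMG low-pass**: Butterworth, cutoff 40 Hz (the diagnostic ECG band is
  concentrated below 40 Hz), applied forward–backward. Order 8: the
  forward–backward pass squares the magnitude response, and order 8 keeps
  the passband within 5% of unity down to 0.8 × cutoff while attenuating
  2 × cutoff by well over 20 dB. (A lower order fails the passband
  requirement once squared: order 4 is already 13% down at 32 Hz.)
* **Powerline notch**: a linear-phase FIR band-stop constructed literally as
  windowed-sinc low-pass (cutoff `f0 − 1` Hz) plus windowed-sinc high-pass
  (cutoff `f0 + 1` Hz), Hamming window, applied with exact group-delay
  compensation. 721 taps (2 s at 360 Hz): the Hamming transition band is
  ≈ 3.3/N of the sampling rate, and 721 taps are needed for that transition
  to fit inside the 1 Hz half-width — at 361 taps the 50 Hz notch only
  reaches ≈ 16 dB, at 721 it exceeds 25 dB while the gain at ±10 Hz stays
  within 0.1% of unity.
* **Baseline high-pass**: Butterworth order 2 at 0.5 Hz, forward–backward.
  0.5 Hz removes most of the 0.05–2 Hz drift band while leaving the QRS
  band (and most P/T energy) untouched; pushing the cutoff into the drift
  band's upper half would start distorting the ST segment.

All three are applied with reflection padding so edge transients do not
leak into the record. The chain is `correct_baseline ∘ notch_powerline ∘
lowpass_emg`; linearity and zero-phase behaviour are asserted by tests.

## Window dataset

Training examples are windows of `2·half_width + 1` samples: positives
centred on annotated R peaks, negatives centred on uniformly drawn positions
at least `min_distance = 25` samples (≈ 70 ms at 360 Hz) from any peak, so
negatives are unambiguous non-R contexts. The ratio is 1:1 for class
balance. Peaks too close to a record boundary to fit a window are skipped,
not padded. Each window is z-score normalised (flat windows map to zeros);
the network is trained and evaluated on that scale, which makes it
insensitive to per-record gain and offset.

The studied half-widths are 50, 75 and 100 (window lengths 101, 151, 201).
The fixed MIT-BIH cross-patient split is built in: records 102 and 104 are
excluded (their first channel is not MLII), the remaining 46 partition into
the canonical 22-record DS1 training list and the 24-record DS2 complement,
and no record ever contributes windows to both sides.

## The residual CNN

The window classifier is a 1-D residual network: one Valid convolution,
two residual blocks of two convolutions each, a final Valid convolution
(six convolutional layers in total), three stride-2 max-pooling layers, one
fully connected layer, and a softmax over {R-centred, not}. ReLU is the
activation throughout. A residual block computes `x + F(x)` where `F` is
conv–ReLU–conv; there is deliberately no activation after the addition, so
zeroing the inner weights makes the block exactly the identity — a property
the tests assert.

Two shape decisions deserve explanation:

* **Padding reconciliation.** Valid (no) padding and shape-preserving
  residual additions cannot both hold everywhere: a Valid convolution
  shortens its input, so `x + F(x)` would be ill-formed. The trunk
  convolutions are Valid; the residual blocks' inner convolutions use
  symmetric ("same") padding so the skip addition is well-formed.
* **Pool kernels.** With stride-2 pooling, a single fixed kernel cannot
  yield integral shape chains for all three input lengths at once (the
  parities diverge). Each pooling layer therefore uses kernel 2 or 3,
  whichever makes `(W − F)/S + 1` an integer. The builder computes every
  layer's output length from the convolution/pooling shape rules at build
  time and errors, naming the layer, on any non-integral chain; an
  instrumented forward pass (`observed_shapes`) verifies at run time that
  the implementation produces exactly the predicted lengths.

Hyperparameters not fixed by the architecture description are declared
choices: kernel length 5, 32 channels throughout the trunk, Adam with
learning rate 1e-3, batch size 128, cross-entropy loss, He-style
initialisation. "Iterations" are training epochs. The seed controls weight
initialisation and batch shuffling, making training reproducible on fixed
hardware/thread settings. The implementation is pure R: convolutions are
im2col reshapes followed by BLAS matrix multiplies, and the backward pass
is the standard hand-derived adjoint of each layer — small networks of this
size train in seconds to minutes on one CPU, which is the regime the test
suite and acceptance script use (≤ 2,000 windows, ≤ 20 epochs; chosen as
comfortably sufficient for the separable synthetic task, where training
accuracy reaches 1.0 within a few epochs).

## Sliding-window detection

The window classifier scores every candidate centre (stride 1 by default;
stride 2–4 trades density for speed and is used where the grid is fine
relative to the 27-sample matching tolerance). Each window is z-score
normalised exactly as in training; zero-variance windows are never
candidates (a flat window carries no beat). Consecutive above-threshold
centres are grouped and each group contributes its maximum-probability
centre; any surviving peak within the 200 ms refractory interval of a
higher-probability peak is suppressed. The output is strictly increasing.

Coverage convention: only centres whose full window lies inside the record
are scored, mirroring the dataset builder's skip-not-pad rule, so beats
closer than `half_width` samples to a boundary are outside the detector's
reach. (Reflection-padding the signal was tried and rejected: the mirrored
R peak lands inside the edge window and distorts its morphology.) Detection
scoring therefore restricts the reference to `interior_peaks()` of the same
half-width — at 360 Hz and half-width 75 this is a 0.2 s strip at each end
of a record.

## HRV features and the intensity SVM

RR intervals in milliseconds come directly from detected peak indices.
Per epoch (default 60 s, 50% overlap; epochs with fewer than 4 peaks are
dropped), the canonical time-domain HRV vector is computed: mean HR,
mean RR, SDNN, RMSSD, pNN50 (threshold 50 ms), and CV-RR. This is the
standard minimal set consistent with HRV-based load monitoring; frequency
domain and nonlinear indices are out of scope.

The intensity classifier is an RBF-kernel SVM, `exp(−γ‖u−v‖²)` with γ = 1
and soft-margin penalty C = 2, multiclass by one-vs-one pairwise voting.
Features are standardised with training-set means and standard deviations
(stored with the model) — without this, γ = 1 would be meaningless across
features whose scales differ by three orders of magnitude (pNN50 vs
mean RR). Vote ties are broken toward the class with the larger aggregate
pairwise decision margin. The binary SVM machinery is `e1071::svm`
(libsvm); the voting and tie-break are applied to its pairwise decision
values. MET labels follow the standard table with the explicit boundary
convention low = [0, 3], medium = (3, 6), high = [6, ∞), which makes the
map monotone.

## Metrics

Accuracy, precision, recall and the β-weighted F-score follow their
standard definitions; β defaults to 1. Metrics with zero denominators are
reported as `NA`, never silently 0. Detected peaks are matched to reference
peaks greedily, one-to-one, within ±75 ms (the conventional QRS-evaluation
window); with references spaced more than twice the tolerance apart — true
of physiological RR at any plausible heart rate — greedy matching attains
the optimal bipartite matching, which the tests verify against an
exhaustive oracle. Cross-group aggregate rates are unweighted means rounded
to two decimals.

## Numerical and degenerate-input choices

* Flat windows normalise to zeros (not NaN) and never become detection
  candidates.
* `average_rates` errors on empty input; `rr_from_peaks` requires ≥ 2
  peaks, `hrv_features` ≥ 3 intervals.
* The 12-bit format-212 WFDB writer clips to [−2048, 2047] ADC units at
  gain 200/mV; readers verify the `.dat` size against the declared sample
  count and refuse truncated files.
* All randomness flows from explicit integer seeds; every generator and
  training routine is a pure function of (inputs, seed).

## Known limitations

* The CNN is CPU-bound pure R; it is sized for the studied window lengths
  and a few thousand training windows, not for training on the full
  MIT-BIH corpus at 100 epochs (the optional harness accepts a
  per-record time cap for exactly that reason).
* The synthetic generator's fixed morphology means detection results on it
  are an upper bound; cross-record generalisation on real arrhythmic data
  is measured only by the optional MIT-BIH harness.
* The HRV feature set and 60 s epoching are declared choices; anyone
  reproducing a specific cohort protocol should confirm its exact feature
  vector and epoch length, which are rarely published.
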