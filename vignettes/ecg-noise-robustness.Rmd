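---
title: "Methods: quantifying classifier robustness to physiological ECG noise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying classifier robustness to physiological ECG noise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Deep classifiers for the electrocardiogram (ECG) are usually trained on
carefully filtered signals, yet deployed on signals carrying physiological
noise: baseline wander from respiration, transients from electrode
movement, broadband muscle artefact. `ecgnoise` implements a desk-scale
version of a noise stress-test protocol for image-transform ECG
classification: build matched clean and noisy versions of one cohort,
convert each signal to two kinds of 150×150 greyscale images, train a
classifier under a fixed cross-validation protocol, and measure how macro
F1 degrades when the noise condition of the test data differs from that of
the training data.

Everything runs from synthetic data, so the pipeline is fully testable
offline; adapters for real CSV/WFDB-style records are provided for
desk-top use.

## The synthetic cohort

`generate_cohort()` emulates a three-class population of 2678 subjects
(976 atrial fibrillation, 918 Normal, 784 ST depression) with lead-II
signals at 500 Hz and record lengths drawn uniformly from 8–138 s. Each
beat is a sum of Gaussian P/QRS/T bumps on a 0 mV isoline — an
ECGSYN-style simplification chosen because it gives controllable
morphology and, crucially, *annotated* fiducials (beat times, ST windows)
that the tests can measure against.

Class structure:

* **Normal** — near-constant RR intervals (coefficient of variation 0.03,
  the scale of respiratory sinus arrhythmia), mean rate 72 bpm, isoelectric
  ST segment.
* **AF** — RR intervals drawn i.i.d. from a gamma distribution with CV 0.2
  and mean rate 115 bpm (above the >100 bpm diagnostic criterion); the P
  wave is replaced by a continuous low-amplitude (0.06 mV) oscillation
  whose frequency drifts over 4–9 Hz, emulating fibrillatory *f* waves.
* **STD** — the Normal morphology with the ST segment displaced downward
  by 0.15 mV (configurable), applied as a smooth plateau whose flat part
  covers the annotated ST window.

Every raw record also carries a white residual noise floor at 30 dB SNR:
real "raw" recordings are nearly, but not exactly, clean, and this keeps
the raw and clean dataset variants distinct. The 30 dB level is a
stand-in for an uncharacterised quantity; it is configurable
(`morphology_params(raw_noise_snr_db = )`).

The cohort is a pure function of its configuration: per-record seeds are
derived from the master seed and the record id, so regeneration is
bitwise identical.

What the generator deliberately does **not** emulate: 12-lead geometry,
beat-to-beat morphology variability, pathological rhythms beyond the three
classes, or the residual mixed noise of real archives. Passing tests
therefore demonstrate that the *protocol* behaves correctly and that the
qualitative robustness ordering emerges under controlled conditions — not
that any particular F1 level transfers to real recordings.

## The noise bank

`generate_noise_bank()` synthesises 30 minutes of each noise process at
the signal sampling rate:

* `bw` — a sum of five sub-0.5 Hz sinusoids with slowly varying random
  amplitudes; ≥ 90% of its spectral power sits below 1 Hz.
* `em` — sparse smooth transients (raised-cosine pulses of 0.5–2.5 s,
  Poisson-distributed starts, about five per minute), near-zero between
  episodes.
* `ma` — broadband Gaussian noise under a slowly varying log-normal
  envelope, giving the bursty amplitude profile of muscle artefact.

`all` is the elementwise sum with fixed weights (1, 1, 1) — the simplest
reading of "a linear combination", recorded in the object so it can be
overridden. All series are zero-mean by construction, and 30 minutes
comfortably covers the longest record (138 s), so segment extraction never
wraps.

## The cleaning chain

`clean_record()` applies, in order: baseline wander removal (0.5 Hz
high-pass), 150 Hz low-pass, 0.05 Hz high-pass, 49–51 Hz notch, and
isoline correction. Filtering is implemented as exact zero-phase
Butterworth magnitude responses applied in the frequency domain on a
reflection-padded signal. This design was chosen over forward–backward
IIR filtering for two reasons: a 0.05 Hz corner at 500 Hz sampling is
numerically fragile as a recursive filter, and the chain must attenuate a
170 Hz tone by ≥ 20 dB with a 150 Hz corner — a transition of only 0.18
octave, which needs the order-10 response used here (≈ 22 dB at 170 Hz;
a 4th-order response would give under 6 dB). The notch is an order-2
band-stop response with exact zero at its centre. All orders and corners
sit in `filter_config()`.

Two conventions worth stating. The high-pass stages zero the sample mean
of their own output exactly (a high-pass has zero DC gain by definition).
"DC offset" of a *cleaned record* is assessed as its electrical zero
level — the mode of the 0.01 mV-binned amplitude histogram, the
conventional isoline estimator — which the final isoline-correction stage
drives to zero exactly. The mode and the arithmetic mean of an ECG differ
(most samples sit on the baseline, the QRS pulls the mean upward), so only
one of them can be exactly zero after a constant shift; the isoline is the
clinically meaningful zero.

The chain is idempotent to within 5% relative RMS, preserves passband
tones to ≥ 95% RMS, and is zero-phase (cross-correlation of input and
output peaks at lag 0).

## SNR-calibrated noise injection

For each clean record, `inject()`: (i) takes the record length; (ii)
draws **one** window offset into the bank, shared by all three noise
types, so the bw/em/ma segments cover the identical time range; (iii)
draws a target SNR uniformly on [5, 10] dB (uniform being the minimal
assumption for "randomly select"); (iv) computes the scaling factor from
the clean signal and the combined `all` segment in closed form,

$$\alpha = \sqrt{\frac{\sum x_{\text{clean}}^2}
                      {\sum x_{\text{all}}^2 \; 10^{T/10}}},$$

(v) scales *all four* segments with that same α; (vi) adds each scaled
segment to the clean signal. SNR is defined on total energy
(`10·log10(Σ signal² / Σ noise²)` over the same sample range). Because α
is closed-form, the realized SNR of the `all` variant equals the drawn
target to floating-point precision; the individual variants inherit α and
are therefore *less* noisy than the target (their component power is at
most the combined power, up to cross-terms). Degenerate inputs
(zero-power noise, raw identical to clean) raise a distinct
undefined-SNR condition rather than returning an infinity.

The per-record draws are keyed by `(record_id, stage seed)`, so the SNR
bookkeeping table is reproducible record by record regardless of
processing order.

## Image transforms

Both transforms consume the full lead-II signal and emit 150×150
greyscale images with intensities in [0, 1] (higher density/magnitude →
higher intensity; no display colormap is baked in).

**SPAR attractor.** The signal is delay-embedded as
$(x(t), x(t-\tau), x(t-2\tau))$ and projected onto the plane orthogonal to
$(1,1,1)$ with the orthonormal basis $v = (x+y-2z)/\sqrt6$,
$w = (x-y)/\sqrt2$; the 2D point density over the symmetric square
$[-r, r]^2$ ($r$ = largest absolute projected coordinate of the record)
is binned on the 150×150 lattice, log1p-scaled and max-normalized. The
delay defaults to one third of the mean cardiac cycle, the cycle length
coming from the autocorrelation peak in the 0.3–3 s lag range; this is
what makes the attractor factor out heart rate, and it falls back to a
fixed delay (with a warning) when no usable peak exists — e.g. for highly
irregular AF records. Choices the underlying method leaves open — the
per-record bounds, the log1p contrast (raw counts are strongly peaked on
the baseline loop), the basis orientation — are fixed in `spar_config()`
for reproducibility. The projection is computed in difference form so a
constant offset of the input cancels exactly in floating point: attractor
images are bit-identical under baseline shifts, the mechanism by which
this transform is inherently insensitive to baseline wander.

**Scalogram.** An analytic Morse wavelet CWT (symmetry γ = 3,
time–bandwidth 60, hence β = 20) at 16 voices per octave, evaluated by
FFT with an L1-normalised wavelet so a unit sinusoid produces a
unit-magnitude ridge at any scale. Frequency limits default to
[max(0.5, 2/T), fs/2] Hz for a record of length T; scale rows run from
high to low frequency. The absolute coefficient matrix is resized to
150×150 — block means where a dimension shrinks (anti-aliasing the long
time axis), bilinear interpolation where it grows — then max-normalized.
Per-image normalization and linear magnitude are the defaults; log
magnitude is a config switch. Resizing every record to the same square,
whatever its duration, means the time axis is uniformly squeezed; two
records of different length have different effective time resolution,
which is inherent to fixed-size scalogram images of variable-length
signals.

`resize_for_network()` provides the bilinear 224/227 rescale used by
standard pretrained input layers; at the native 150 it is an exact
identity.

## Folds, training, early stopping

`make_folds()` produces the predefined splits reused by every image
dataset: 5 test partitions, pairwise disjoint and covering all records
(20% each), stratified by class, with the remainder split 5%/75% into
validation and training per fold. Rounding is deterministic — per-class
test remainders are assigned round-robin with an offset carried across
classes, which keeps total test sizes within one of each other (2678
records give sizes 535/536); the validation quota is `round(0.05 n)`
distributed by largest remainder. Stratification stabilises per-class F1
at small n and can be switched off by shuffling labels upstream.

The classifier is deliberately compact. The default backbone pools each
image to 16×16 and feeds a multinomial softmax head trained by full-batch
gradient descent with momentum — a convex problem with a zero
initialisation, so training is exactly reproducible with no weight
randomness. A second backbone mirrors the frozen-backbone /
replaced-head shape of transfer learning: a frozen bank of eight seeded
random 5×5 convolution filters with ReLU and average pooling, on top of
which only the softmax head is trained. The harness contract — predefined
folds, per-epoch validation loss, patience-5 early stopping, swappable
backbone — is what carries the study's conclusions; any backbone
implementing `train`/`predict` can be substituted.

Early stopping follows the literal rule: a counter increments on each
epoch whose validation loss exceeds the running minimum and resets to
zero whenever a new minimum is achieved; training halts when the counter
reaches the patience (default 5) or at `max_epochs` (default 50). A loss
exactly equal to the running minimum neither increments nor resets. The
returned model carries the weights of the best-validation epoch.
Validation loss is evaluated once per epoch.

## Metrics and the experiment grid

Per class, precision = TP/(TP+FP), recall = TP/(TP+FN),
F1 = 2PR/(P+R); macro F1 is the arithmetic mean of the three class F1s.
Any zero denominator yields 0 — the conservative convention, affecting
only degenerate folds. `run_variation()` implements the three protocol
variations (train/test within each dataset; train on clean, test on all
variants; train on combined noise, test on all variants), always
fold-matched: a model fitted on fold f is applied only to fold f's test
partition of the target variant, the only leakage-safe reading of
cross-dataset testing. Cells report mean ± sd across the five folds, and
the per-fold raw predictions ride along as an attribute so every cell is
recomputable without retraining.

## Problem sizes

The package's own experiment scale, used by its tests: the robustness
contrast runs on a 300-record cohort (100 per class) with record lengths
drawn from 8–20 s, both transforms, five folds, five master seeds, and
the compact backbone; protocol-exactness checks (SNR calibration, fold
combinatorics) use 200-record cohorts and scripted sequences. These sizes
keep a full run on one CPU in the minutes range while leaving each class
several hundred images across folds. At this scale the synthetic classes
are cleanly separable, so same-condition F1 sits far above the published
values for real data — the object of comparison is the *ordering* of
train/test conditions, not the F1 levels.

## Numerical choices and degenerate inputs

* SNR calibration is closed-form; the round-trip tolerance asserted in
  tests is 1e-9 dB.
* A fully degenerate projected point set (constant signal) renders as a
  single-pixel image rather than an error.
* Cycle-estimation failure falls back to the configured fixed delay with
  a warning, never an error.
* Histogram binning uses half-open bins with the top edge closed;
  prediction arg-max ties break toward the first class in (AF, Normal,
  STD) order, deterministically.
* All stage seeds derive from one master seed via a stable string hash,
  and every derived seed stays below 2^31.

## Limitations

The generator's separability makes absolute F1 values optimistic;
conclusions should be read as orderings. Single-lead only. The filtering
chain is a re-implementation of the *kind* of cleaning used on real data,
not of any specific toolbox's internals; per-class filter behaviour (a
known confounder on real pathological ECGs) is not modelled. The
mode-based isoline estimator interacts with AF's continuous f-wave
oscillation (whose amplitude histogram peaks at its extremes), which
slightly offsets cleaned AF records relative to their raw counterparts —
visible as a lower raw-signal SNR for AF; this mirrors the behaviour of
histogram-mode isoline correction on real fibrillatory signals.
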