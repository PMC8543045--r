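# ecgnoise

How robust is image-transform ECG classification to physiological noise?
`ecgnoise` is an R package implementing a desk-scale noise stress-test
pipeline for electrocardiogram (ECG) classifiers: it builds matched clean
and noisy versions of a labelled ECG cohort, converts every lead-II signal
into two kinds of 150×150 greyscale images, trains a classifier under a
predefined cross-validation protocol, and measures how macro F1 degrades
when the noise condition of the test data differs from that of the
training data.

It is aimed at researchers studying classifier robustness and at anyone
who needs a fully reproducible, download-free harness for ECG noise
experiments: every input — the three-class cohort (atrial fibrillation,
Normal, ST depression) and the 30-minute physiological noise bank
(baseline wander `bw`, electrode movement `em`, motion artefact `ma`, and
their combination `all`) — is generated synthetically, with adapters for
real CSV/WFDB-style records.

## The method in brief

* **Six dataset variants per cohort.** `raw` → zero-phase filtering chain
  (baseline removal, 150 Hz low-pass, 0.05 Hz high-pass, 49–51 Hz notch,
  isoline correction) → `clean` → SNR-calibrated injection → `bw`, `em`,
  `ma`, `all`. For each record one noise window and one target SNR
  *T* ~ U[5, 10] dB are drawn, and one scaling factor

  α = √( Σx²_clean / (Σx²_all · 10^(T/10)) ),   SNR = 10·log₁₀(Σx²_s / Σx²_n)

  scales all four noise segments, so the realized SNR of the `all`
  variant equals the target exactly.
* **Two image transforms.** The SPAR attractor — delay embedding
  (x(t), x(t−τ), x(t−2τ)) with τ = cycle/3, projection onto the plane ⟂
  (1,1,1), 150×150 point-density image; exactly invariant to baseline
  offsets — and the analytic Morse wavelet scalogram (γ = 3,
  time–bandwidth 60, 16 voices per octave), |CWT| resized to 150×150.
  6 variants × 2 transforms = 12 image datasets.
* **Fixed protocol.** Predefined stratified 75/5/20
  train/validation/test folds (k = 5) reused by all 12 image datasets;
  patience-5 early stopping on the per-epoch validation loss; per-class
  precision/recall/F1 and macro F1 reported as mean ± sd across folds,
  for three variations: train/test within each dataset, train on clean →
  test on everything, train on `all` noise → test on everything.

## Worked example

Train on the clean image datasets and classify every variant (60-record
cohort, 5 folds):

```r
library(ecgnoise)

cfg <- run_config(
  cohort = cohort_config(n_af = 20, n_normal = 20, n_std = 20,
                         duration_range = c(8, 12), seed = 42),
  train  = train_config(max_epochs = 30),
  k = 5, variations = "clean_train", seed = 42)
res  <- run_study(cfg)
summ <- summarize_metrics(res$metrics)
subset(summ, class == "macro")
```

```
      kind train_variant test_variant mean_f1 sd_f1
 attractor         clean          all   0.511 0.129
 attractor         clean           bw   0.947 0.118
 attractor         clean        clean   0.942 0.130
 attractor         clean           em   0.882 0.127
 attractor         clean           ma   0.778 0.209
 attractor         clean          raw   0.942 0.130
 scalogram         clean          all   0.606 0.128
 scalogram         clean           bw   0.983 0.038
 scalogram         clean        clean   1.000 0.000
 scalogram         clean           em   0.807 0.131
 scalogram         clean           ma   0.966 0.046
 scalogram         clean          raw   1.000 0.000

realized all-noise SNR range: 5.15 to 10.00 dB
```

Reading the table: each row is a (transform, test dataset) cell with the
macro F1 mean ± sd over the 5 folds of a model trained on *clean* images.
Performance on `raw` matches `clean` (raw records carry only a high-SNR
residual floor), baseline wander barely hurts — the attractor is exactly
offset-invariant and the drift sits below the scalogram's informative
band — while electrode movement, motion artefact and especially the
combined `all` noise cut macro F1 sharply. The synthetic classes are
cleanly separable, so absolute values sit above what real cohorts give;
the object of interest is the ordering across conditions. The
complementary contrast (`robustness_experiment()`) shows the reverse
direction is far cheaper: models trained on `all` noise lose little when
classifying clean images.

Useful entry points: `generate_cohort()`, `generate_noise_bank()`,
`clean_record()`, `inject()`, `spar_attractor()`, `cwt_scalogram()`,
`make_folds()`, `train_classifier()`, `run_variation()`,
`robustness_experiment()`, `run_study()`; `autoplot()` renders images and
training histories, `tidy()`/`glance()` summarise folds and fitted
classifiers. A thin CLI over `run_study()` lives at
`inst/cli/ecgnoise.R`.

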