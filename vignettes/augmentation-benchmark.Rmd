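---
title: "Benchmarking data augmentation for heart-sound spectrogram classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking data augmentation for heart-sound spectrogram classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgaug)
```

## The problem

Phonocardiogram (PCG) classification asks whether a recorded heart sound is
normal or abnormal. A healthy cardiac cycle contains two transients — S1
(atrioventricular valve closure) and S2 (semilunar valve closure) —
separated by a quiet systole (about a third of the cycle) and diastole.
Pathological sounds contain *additional* frequency components: murmurs
(band-limited noise from turbulent flow through stenotic or regurgitant
valves, typically well above the S1/S2 bands), or low-frequency S3/S4
gallops. Heart rates sit in a narrow 60–100 beats/min range and essentially
all heart-sound energy lies between 20 and 500 Hz.

A standard recognition pipeline renders each recording as a Mel-spectrogram
colour image and trains a small convolutional network on the images.
Because labelled clinical recordings are scarce, data augmentation —
synthesising one transformed copy of every training item, doubling N to 2N —
is attractive, but audio- and image-level transformations interact with the
physiology in non-obvious ways (injected white noise literally *is* a
murmur-like component; flipping the frequency axis scrambles the spectral
content). This package implements the full comparison harness: a synthetic
PCG generator, the preprocessing and spectral-imaging pipeline, ten
augmentation arms plus an un-augmented baseline, a fixed CNN, and a
stratified cross-validation evaluator with fold-paired confidence
intervals.

## The synthetic generator

The generator (`generate_recording()`, `generate_dataset()`) is a
first-class, tested component: it supplies data with the statistical
structure the analysis assumes, so every downstream stage can be exercised
without any clinical download.

* Each cycle places a Gaussian-windowed tone burst for S1 (~100 ms, centre
  frequency uniform in 30–100 Hz) and S2 (~80 ms, 50–150 Hz, 0.8 relative
  amplitude) at the sampled heart rate; systole occupies one third of the
  cycle. Per-beat amplitude jitter (±10%) adds realism.
* Abnormal recordings carry exactly one extra component: a systolic or
  diastolic murmur (Gaussian noise band-limited to 150–400 Hz, gated to the
  corresponding interval by a raised-cosine envelope) or an S3/S4 gallop
  (a 70 ms, 20–70 Hz transient after S2 / before S1).
* `murmur_snr` sets the murmur RMS relative to the S1/S2 train; the default
  −6 dB is a loud but clinically plausible murmur. The default component
  mix is murmur-dominated (systolic 0.65, diastolic 0.33, S3 0.01,
  S4 0.01): murmurs are the chief discriminator of the abnormal class in
  the source corpus, and an energy threshold on the murmur band is required
  (and tested) to separate the classes at ROC AUC ≥ 0.95 — a contract that
  gallop-only recordings, which carry no murmur-band energy at all, would
  dilute at roughly 1/82 AUC per drawn gallop.
* A white noise floor sits at −50 dB, and the finished signal is gently
  shaped by a second-order 20–500 Hz Butterworth pass. The shaping matters
  for low S1 draws: a Gaussian burst centred at 30 Hz otherwise leaks
  appreciable power below 20 Hz, violating the in-band power contract
  (< 5% of spectral power outside 20–500 Hz).
* Sample rate defaults to 2000 Hz, the convention of the public
  heart-sound challenge corpora. Durations are uniform on 6–60 s, so the
  length policy below has something to do. The class ratio defaults to
  2189:560 ≈ 3.9:1.

What the generator does **not** emulate: subject-level clustering (each
recording is independent, so cross-validation here is record-wise, not
subject-wise), respiratory modulation and split S2, sensor/handling noise,
and any per-pathology acoustic signature beyond "extra components". Passing
tests therefore demonstrate that the pipeline machinery is correct and that
the comparison harness can detect separable classes — not that any
particular augmentation will help on clinical data.

## Preprocessing

`preprocess_recording()` applies, in order: a third-order Butterworth
band-pass at 20–500 Hz, the length policy (recordings under 8 s are
discarded; anything over 30 s is truncated to its first 30 s; exactly 8 s
and exactly 30 s are kept), and peak normalisation \(x / \max|x|\), which
makes the later 0 dB spectrogram reference comparable across recordings.
The filter runs zero-phase (forward–backward), so S1/S2 onsets are not
shifted by group delay; the effective magnitude response is the squared
design response, which only sharpens the band edges. Normalisation comes
last so the peak is measured post-filter. An all-zero signal has no defined
normalisation and errors.

## Spectral imaging

`power_spectrogram()` frames the signal with a 512-sample Hann window at
hop 256 and a 512-point FFT, with no padding (frame count
`floor((n − 512)/256) + 1`). The Mel scale used is

\[ Mel(f) = 2595\,\log_{10}\!\left(1 + f / b\right), \qquad b = 500, \]

with the break frequency of 500 Hz as configured by default; the
conventional 700 Hz variant is available via `mel_break_hz` (the 2595
coefficient pins the map to base-10 logarithms). A 128-channel triangular
filterbank spans 0 to Nyquist on that scale. Amplitudes are converted to
decibels with the maximum as the 0 dB reference —
\(20\log_{10}(A/A_{max})\) with \(A = \sqrt{P}\), identically
\(10\log_{10}(P/P_{max})\), so the amplitude- and power-dB conventions
coincide and no separate switch is needed — and clamped at a −80 dB floor
that bounds the colour mapping. `render_image()` sends dB through a
perceptually uniform dark-to-yellow palette ("Inferno"; the 0 dB maximum
renders yellow/bright) and resizes the result to exactly 100 × 180 × 3 by
Keys bicubic interpolation (a = −0.5), low frequencies at the bottom row.
The 100 × 180 size is read as rows × columns (frequency × time); channel
count, colormap, dB floor and Mel channel count are all configuration,
since none is intrinsic to the method.

## The augmentation arms

All arms are one-to-one: each training item contributes exactly one
augmented copy with the same label; test folds are never augmented.

| arm | method | level |
|-----|--------|-------|
| 0 | none (baseline) | — |
| 1 | pitch shift (±1–10 semitones) then time stretch (t ∈ [0.5, 2]) | audio |
| 2 | additive white Gaussian noise, σ = RMS(signal) (0 dB SNR) | audio |
| 3.1 / 3.2 | horizontal / vertical flip | image |
| 4.1 | saturation/value perturbation (blend weights U(0.5, 2), U(0.1, 2)) | image |
| 4.2 | PCA colour augmentation, α ~ N(800, 10²) | image |
| 4.3 | random colour filter (150-entry registry) | image |
| 5 | 3 time + 3 frequency masks, widths U{0..20} | Mel matrix |
| 6 / 7 | PCA → hflip, SV → hflip | image |

Numerical choices worth stating:

* **Pitch and time.** Pitch shift preserves duration and time stretch
  preserves pitch (phase-vocoder contracts); the sign of the semitone count
  is up/down with probability ½. The vocoder uses Hann analysis/synthesis
  windows of 512 with synthesis hop 128 and standard per-bin phase
  propagation; pitch shifting stretches by \(2^{p/12}\) and resamples back
  to the original length.
* **Noise.** The noise vector is the one and only random draw under the
  item seed, so realisations are reproducible; the sum is re-normalised by
  its peak to stay in [−1, 1] (the realised noise RMS is recorded in the
  provenance so the empirical SNR can be read off).
* **SV.** Brightness pass (blend with black) before saturation pass (blend
  with the image's own BT.601 grayscale); the printed blend
  `Blend*(1−α) + Original*α` is the identity at α = 1.
* **PCA.** The 3×3 RGB covariance is computed per image on the raw 0–255
  scale (a dataset-wide covariance can be supplied via `stats`), a single
  α scales all three eigenvalues, and the shift `V(αλ)` is added to every
  pixel. Eigenvectors are defined only up to sign, which would make the
  operation ill-defined; the package fixes each eigenvector so its
  largest-magnitude component is positive.
* **Colour filters.** The registry enumerates exactly 150 distinct
  3-channel conversions: {RGB, HSV, HLS, YUV, YCrCb, XYZ, LAB, LUV, YIQ} ×
  6 channel permutations × {normal, inverted} (108), plus 42 chained
  two-space conversions. Entry 1 is the identity; conversions that change
  channel count are excluded by construction.
* **Masking.** Operates on the Mel dB matrix before colormapping, with
  integer widths drawn from {0, …, 20} (channels and time steps are
  discrete), three masks per domain, independent locations (overlap
  allowed), and fill value 0 dB — the colormap maximum, so masks render as
  bright bars. Frequency starts are drawn from the open interval
  (0, v − f), time starts from the closed [0, τ − t], as specified.

## The classifier

The CNN is architecturally frozen across arms: conv(32, 3×3, stride 1,
valid, ReLU) → maxpool(2×2, stride 2) → conv(64, 3×3, valid, ReLU) →
maxpool(2×2) → flatten (63,296 wide for 100×180×3) → dense(64, ReLU) →
dense(1, sigmoid), trained with Adam on binary cross-entropy for exactly
10 epochs. Unstated hyper-parameters are fixed as: batch size 32, learning
rate 10⁻³, pixel intensities scaled to [0, 1], He-scaled normal weight
initialisation. Weights are re-initialised per fold from a fold-specific
seed that is shared across arms, and `model_spec_hash()` asserts that no
arm drifts from the common spec. The implementation (Rcpp/RcppArmadillo)
lays each minibatch out as concatenated im2col blocks so every layer runs
as one large single-threaded BLAS call; arithmetic is float32 and training
is bit-deterministic for a fixed seed and example order.

## Evaluation

One stratified fold plan (per-fold class proportion within one sample of
the global proportion) is built per experiment and shared by every arm;
`fold_hash()` certifies the sharing. Per fold we report accuracy and F1 at
the 0.5 threshold, ROC AUC (trapezoid over all thresholds — equal to the
pairwise concordance statistic, which the tests exploit as an oracle),
PR AUC (step interpolation, the average-precision convention), and
specificity at ~90% sensitivity, resolved without interpolation as the
operating point with the smallest sensitivity still ≥ 0.90. Arms are
compared to the baseline by fold-paired mean differences with a paired
t interval, \( \bar d \pm t_{0.975,k-1}\, s_d/\sqrt{k} \), and the CI-zero
decision rule. k = 5 by default; the CI construction and k are design
choices (neither is forced by the decision rule itself), and the default
classification threshold 0.5 is likewise a convention.

Degenerate cases are pinned down: F1 with no predicted positives is 0 with
a warning; a single-class score set is an error; an all-tied score vector
admits only the two trivial operating points, so specificity at 90%
sensitivity is 0 there.

## Problem sizes

The shipped tests and the acceptance script run the baseline arm at the
study's desk-scale conditions — 400 synthetic recordings at ≈3.9:1
imbalance (318:82), k = 5, 10 epochs — and verify that the baseline CNN
reaches mean ROC AUC ≥ 0.90 on held-out folds. The all-arm structural
checks (every arm completes, one-to-one doubling, shared fold plan, no
test-fold leakage) run on a smaller 30-recording dataset with a one-epoch
model spec: those properties are invariant to training length, and this
keeps a full 11-arm sweep proportionate for a routine test run. A full
11-arm, 10-epoch comparison at 400 recordings is a single
`run_experiment(experiment_config())` call for anyone prepared to let it
run for a few hours on one core.

## Known limitations

* Record-wise (not subject-wise) cross-validation; the generator has no
  subject identity. Leave-one-subject-out evaluation is out of scope.
* The synthetic abnormal class is deliberately simple (one extra component
  per recording); absolute metric values on synthetic data say nothing
  about clinical performance, only about the harness.
* The real-corpus mode (`read_wav_directory()` + the same pipeline)
  supports reproducing the clinical preprocessing counts, but the package
  ships no clinical audio; that path is tested on a synthetic stand-in
  directory.
* Wavelet/constant-Q representations and resampling-based class
  rebalancing are intentionally not implemented.

## A worked call

```{r example, eval = FALSE}
cfg <- experiment_config(
  n_normal = 24, n_abnormal = 8,
  pcg = pcg_config(duration_range = c(9, 15)),
  model = model_spec(epochs = 2),
  k = 4, arms = c("0", "3.1", "5"), seed = 11
)
rep <- run_experiment(cfg)
glance(rep)            # per-arm means with 95% CIs
rep$comparisons        # fold-paired differences vs. the baseline
autoplot(rep)          # CI plot; plot_curves(rep, "roc") for curves
write_report(rep, "report/")
```
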