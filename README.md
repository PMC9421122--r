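# pcgaug

Benchmarking data-augmentation strategies for heart-sound classification
from Mel-spectrogram images.

## What this is for

Automated phonocardiogram (PCG) screening pipelines render each heart-sound
recording as a Mel-spectrogram colour image and train a convolutional
network to call it normal or abnormal (abnormal sounds carry extra
frequency components: murmurs, S3/S4 gallops). Labelled recordings are
scarce, so training sets are commonly doubled by data augmentation — but
augmentations that help on everyday images or speech can be actively
harmful here (injecting white noise manufactures murmur-like content;
flipping the frequency axis scrambles the spectral code). `pcgaug` is a
reproducible harness for measuring exactly that, aimed at researchers in
biomedical signal analysis:

* a physiologically structured **synthetic PCG generator** (S1/S2 bursts at
  60–100 bpm, 20–500 Hz energy, gated murmur noise, gallop transients,
  ~3.9:1 class imbalance) so the whole pipeline is testable offline;
* **preprocessing**: third-order Butterworth 20–500 Hz band-pass
  (zero-phase), discard < 8 s / truncate > 30 s, peak normalisation
  x / max|x|;
* **spectral imaging**: Hann 512 / hop 256 / 512-point FFT,
  Mel = 2595·log10(1 + f/500) (break configurable to 700), 128-channel
  filterbank, dB with max = 0 dB reference, −80 dB floor, rendered through
  a dark-to-yellow colormap and bicubic-resized to 100 × 180 × 3;
* **ten augmentation arms** plus baseline, each one-to-one (N → 2N):
  pitch shift ±1–10 semitones + time stretch [0.5, 2] (phase vocoder),
  AWGN at 0 dB SNR (σ = RMS), horizontal/vertical flips,
  saturation/value blending, PCA colour augmentation (α ~ N(800, 10²)),
  a 150-entry random colour-filter registry, 3 + 3 time/frequency masks
  (widths 0–20, fill 0 dB), and PCA→hflip / SV→hflip compositions;
* the **fixed CNN**: conv 32×(3×3) → maxpool → conv 64×(3×3) → maxpool →
  flatten (63,296) → dense 64 → sigmoid, Adam, binary cross-entropy,
  10 epochs (Rcpp/RcppArmadillo, single-threaded, bit-deterministic);
* **evaluation**: one stratified k-fold plan shared by all arms (hash
  asserted), ROC AUC, PR AUC, F1, accuracy, specificity at ~90%
  sensitivity, and fold-paired mean-difference 95% CIs against the
  baseline with the CI-zero significance rule.

## Worked example

```r
library(pcgaug)

cfg <- experiment_config(
  n_normal = 24, n_abnormal = 8,
  pcg   = pcg_config(duration_range = c(9, 15)),
  model = model_spec(epochs = 2),
  k = 4, arms = c("0", "1", "3.1", "4.2", "5"), seed = 11
)
rep <- run_experiment(cfg)
glance(rep) |> dplyr::filter(metric == "roc_auc")
```

```
#> # A tibble: 5 × 6
#>   arm   method     metric   mean conf.low conf.high
#>   <chr> <chr>      <chr>   <dbl>    <dbl>     <dbl>
#> 1 0     baseline   roc_auc 0.875    0.477      1.27
#> 2 1     pitch_time roc_auc 0.979    0.913      1.05
#> 3 3.1   hflip      roc_auc 0.896    0.564      1.23
#> 4 4.2   pca        roc_auc 0.938    0.739      1.14
#> 5 5     mask       roc_auc 0.875    0.477      1.27
```

Each row is one experiment arm: the mean held-out ROC AUC across the four
shared folds with its 95% t interval (at this toy size the intervals are
wide; the full-scale defaults use 400 recordings and k = 5).
`rep$comparisons` holds the fold-paired mean differences against arm 0
with the CI-zero significance call, `tidy(rep)` the per-fold metrics,
`autoplot(rep)` / `plot_curves(rep, "roc")` the standard figures, and
`write_report(rep, dir)` writes CSV/JSON tables plus ROC/PR curve PNGs.

Individual stages are exported too: `generate_dataset()`,
`preprocess_recording()`, `spectrogram_image()`, `pitch_shift()`,
`inject_awgn()`, `hflip()`, `pca_color_augment()`,
`time_frequency_mask()`, `train_cnn()`, `roc_pr_curves()`,
`stratified_folds()` … A directory of real labelled WAVs can be swapped in
for the generator with `experiment_config(data_dir = ...)`
(PhysioNet-style `REFERENCE.csv` labels).

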