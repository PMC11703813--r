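# bruitnet

Classification of arteriovenous-fistula (AVF) shunt sounds — the "bruit"
heard over a hemodialysis patient's vascular access — into **normal** and
**abnormal** (stenotic) classes, for researchers in biomedical acoustics
and physiological signal classification.

A stenosed fistula (lumen below about 1.8 mm) changes the turbulence
sound recorded by an electronic stethoscope: spectral energy drops and
becomes scattered instead of uniformly distributed across frequency.
`bruitnet` implements a complete, reproducible pipeline that exploits
this contrast:

1. **Synthetic bruit generator** — seeded 24–30 s, 16 kHz waveforms with
   a controllable normal/abnormal spectral contrast (`separation`
   in \[0, 1\]), so every downstream stage is testable without access to
   clinical recordings.
2. **Augmentation** — additive white noise at a prescribed SNR and
   random clipping into 3–6 s and 18–21 s segments, expanding 600 normal
   + 200 abnormal originals into a balanced 1,200 + 1,200 set, split
   70/10/20 into train/validation/test (1,680 / 240 / 480).
3. **Feature fusion** — pre-emphasis `y[n] = x[n] − 0.97·x[n−1]`,
   a 128-band log-Mel spectrogram (25 ms Hann window, 10 ms hop) resized
   to 128 frames, 13 MFCCs from the same framing, two-stage column-wise
   min–max normalization, and concatenation into a `(128, 141, 1)`
   network input.
4. **CBAM-LSTM classifier** — three convolutional blocks
   (64/128/256 3×3 filters, LeakyReLU, batch norm, convolutional block
   attention, 2×2 max pooling, dropout), an LSTM over the 16 remaining
   time steps, and a sigmoid output; trained with Adam (lr 0.001,
   batch 64, early stopping) on binary cross-entropy

   L = −(1/N) Σᵢ \[ yᵢ log ŷᵢ + (1 − yᵢ) log(1 − ŷᵢ) \].

   The network, including backpropagation through the attention module
   and the LSTM, is implemented in package R code and verified against
   finite-difference gradients.
5. **Evaluation** — confusion matrix with Precision = TP/(TP+FP),
   Recall = TP/(TP+FN), F1, Accuracy; AUROC via the Mann–Whitney rank
   statistic; and PSNR = 10·log₁₀(MAX²/MSE) / single-window SSIM for
   quantifying the between-class difference of feature images.

## Worked example

```r
library(bruitnet)

# a small cohort: 30 normal + 10 abnormal synthetic bruits
config <- run_config(
  n_normal = 30, n_abnormal = 10, separation = 0.8,
  model = model_config(conv_filters = c(4L, 8L, 12L), cbam_reduction = 4L,
                       cbam_kernel = 3L, lstm_units = 24L, dense_units = 16L,
                       batch_size = 16L, max_epochs = 12L),
  compare_n = 10, global_seed = 7)
res <- run_pipeline(config, out_dir = "run1", verbose = FALSE)
res$report
#> <eval_report> n=24  TP=12 FP=0 TN=12 FN=0
#>   precision 1.0000  recall 1.0000  F1 1.0000  accuracy 1.0000  AUROC 1.0000
res$comparison
#> # A tibble: 3 x 4
#>   feature         psnr_db  ssim n_pairs
#>   <chr>             <dbl> <dbl>   <int>
#> 1 Mel spectrogram    20.9 0.808      10
#> 2 MFCC               17.7 0.880      10
#> 3 Fused feature      20.4 0.827      10
```

The evaluation report counts held-out test predictions: the 40
originals expand to 120 balanced recordings, 24 of which form the test
set, and at `separation = 0.8` the synthetic classes are fully
separable, so every test clip is classified correctly and AUROC is 1.
The comparison table quantifies how different a normal/abnormal pair of
feature images looks under each representation — lower PSNR and SSIM
mean a larger between-class difference. (With clinical recordings this
table is the basis for choosing the fused representation; the synthetic
generator makes the classes distinguishable under all three.)
Per-stage functions (`generate_dataset()`, `expand_and_balance()`,
`split_dataset()`, `featurize()`, `build_model()`, `train_model()`,
`predict()`, `confusion_and_metrics()`, `roc_auc()`,
`compare_feature_types()`) expose every intermediate step; `autoplot()`
methods draw training traces and ROC curves, and `plot_fused_feature()`
renders a feature image. A thin command-line front end is installed as
`exec/bruitnet` (subcommands `simulate`, `run-all`,
`compare-features`).

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "bruitnet", load_package = "installed")'
```

The suite covers WAV I/O round trips, generator invariants and
class-separability, augmentation arithmetic, feature-fusion shapes and
oracles (direct DCT-II summation, mel-scale band centers), CBAM
forward/backward checks against hand-computed passes and finite
differences, loss/metric closed forms, and scaled-down end-to-end
training runs.

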