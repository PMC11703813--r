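---
title: "Classifying arteriovenous-fistula shunt sounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying arteriovenous-fistula shunt sounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bruitnet)
```

## The problem

An arteriovenous fistula (AVF) is the surgically created artery–vein
connection used as vascular access in hemodialysis. Blood rushing
through the anastomosis produces an audible turbulence sound (a *bruit*
or shunt sound). When the fistula stenoses — clinically, when its lumen
narrows below about 1.8 mm — the hemodynamics change and so does the
sound: overall spectral energy falls and its distribution over frequency
becomes scattered rather than uniform. `bruitnet` implements a full
pipeline that classifies 24–30 s stethoscope recordings of the bruit as
*normal* or *abnormal* from that spectral contrast.

Because clinical AVF recordings are private, the package ships a
synthetic bruit generator as a first-class, tested module; every stage
downstream of ingestion is exercised end to end on its output.

## The synthetic bruit generator

`generate_bruit()` models a recording as low-passed Gaussian turbulence
amplitude-modulated by a systolic pulse train:

* broadband turbulence: white Gaussian noise through a 2nd-order
  Butterworth low-pass with a 2 kHz corner, normalized to unit variance;
* systolic modulation: Gaussian bumps (σ = 45 ms, amplitude 1.6 over a
  0.35 baseline) centred on each beat of a 1.2 beat/s (72 bpm) pulse
  train with 10 ms timing jitter.

For the abnormal class, a single effect-size knob `separation` ∈ [0, 1]
controls three departures: the waveform is attenuated by
`1 − 0.5·separation` (lower total energy), the turbulence corner
narrows by the factor `1 − 0.6·separation` (energy concentrated at low
frequency, i.e. no longer uniform), and Poisson-timed narrowband tone
bursts (σ = 20 ms, 2.5–6 kHz, amplitude `0.45·separation`) are
superimposed (scattered energy). At `separation = 0` the two classes are
draws from the same distribution, giving a clean null for testing. All
draws are seeded; each dataset entry derives its own child seed, so
generation is bit-reproducible.

What the generator does *not* emulate: patient covariates, stethoscope
transfer functions, contact noise, or any hemodynamic model linking
lumen diameter to sound. Passing tests on synthetic data therefore
demonstrate that the pipeline's machinery is correct and that it can
recover a class contrast of the stated *kind* — not that it attains any
particular accuracy on clinical recordings.

Default study conditions follow the clinical cohort structure: 600
normal and 200 abnormal originals of 24–30 s at 16 kHz; `separation`
defaults to 0.8, a value at which a simple 0–2 kHz band-power threshold
already separates classes almost perfectly (the tests verify
monotonicity of that separability in the knob).

## Augmentation and splitting

Two augmentations expand and balance the dataset:

* `add_white_noise()` adds seeded Gaussian noise scaled to an exact
  target SNR (default 20 dB; the level is a package choice — only the
  operation itself is prescribed);
* `clip_segments()` cuts one 3–6 s and one 18–21 s contiguous segment at
  seeded uniform starts.

`expand_and_balance()` applies multiplicities chosen as the minimal
scheme consistent with both operations and the 600/200 → 1,200/1,200
balance: each normal original contributes its two clips; each abnormal
original contributes its two clips, a full-length noise-augmented
variant with its two clips, and the full-length clean recording. A noisy
clip is produced by clipping the noise-augmented variant, so provenance
stays within the four-value vocabulary (`original`, `noise_augmented`,
`clip_3_6`, `clip_18_21`) and composition is recorded through
`parent_id`.

`split_dataset()` partitions at ratios 0.7/0.1/0.2, stratified by label
(stratification stabilizes metrics on the small validation set). Subset
sizes are `floor(N·ratio)` for validation and test with the remainder
in train, apportioned across classes by largest remainder — this
reproduces both 2,400 → 1,680/240/480 and the 10 → 7/1/2 small-sample
case with at most one recording of class imbalance per subset. Splitting
happens after augmentation, so siblings of one original can land in
different subsets; that mirrors the published procedure, and with fully
synthetic data the leakage concern is moot. Grouped splitting by parent
can be had by splitting the original manifest first and expanding each
part separately.

## Feature fusion

The front end converts a waveform of any duration from 3 to 30 s into a
fixed `(time = 128, feature = 141, channel = 1)` array:

1. **Pre-emphasis** `y[n] = x[n] − μ·x[n−1]`, μ = 0.97 (first sample
   passed through), boosting high frequencies before spectral analysis.
   Its transfer magnitude is 1 − μ = 0.03 at DC and rises monotonically
   to 1 + μ at Nyquist; both facts are tested from the impulse response.
2. **Framing**: 25 ms Hann window, 10 ms hop (400/160 samples at
   16 kHz), no padding; FFT length 512.
3. **Mel spectrogram**: 128 triangular bands on the HTK mel scale
   `2595·log10(1 + f/700)` from 0 Hz to Nyquist; power floored at 1e-10
   before `10·log10` so digital silence yields a finite constant matrix.
4. **MFCC**: orthonormal DCT-II of each frame's 128 log-mel powers,
   keeping coefficients 0–12.
5. **Time standardization**: linear interpolation of the frame axis to
   128 columns. Interpolation (rather than cropping or padding) is used
   because clip durations legitimately range from 3 to 21 s and every
   clip must map to the same resolution.
6. **Two-stage normalization**: each time-frame column is min–max
   mapped to [0, 1]; the normalized mel (128 rows) and MFCC (13 rows)
   matrices are stacked into a (141, 128) matrix; the columns are
   normalized again so the two feature families share one scale; the
   result is transposed and given a singleton channel axis.

Numerical conventions worth noting: constant columns normalize to zero
(the 0/0 case is undefined; zero keeps the [0, 1] range invariant and is
idempotent); the MFCC matrix is stored as (13, 128) so the row-block
concatenation is well-typed, treating the transposed orientation as the
same object; the Hann window is the periodic variant; windows, mel
variant (HTK) and FFT length are standard speech-processing defaults.

## The CBAM-LSTM classifier

`build_model()` assembles, per convolutional block `k` ∈ {64, 128, 256}
filters: `conv 3×3 → LeakyReLU(0.01) → batch norm → CBAM → max-pool 2×2
→ dropout(0.3)`. After three blocks the `(128, 141)` input is reduced to
16 time steps × 17 features × 256 channels; the time axis becomes a
16-step sequence of 17·256-dimensional inputs to an LSTM (128 units,
forget-gate bias 1), whose final hidden state feeds
`dense(64) + LeakyReLU + dropout` and a single-logit output. The sigmoid
head is implied by the binary cross-entropy objective; training with
Adam (learning rate 0.001, batch 64, up to 300 epochs) monitors
validation loss with patience 10 and restores the best weights. A
prediction is *abnormal* when its probability is ≥ 0.5; the tie goes to
abnormal deliberately, favouring sensitivity in a screening context.

**The attention module.** Channel attention pools the feature map over
space by both mean and max, passes the two C-vectors through a shared
bottleneck MLP (C → C/r → C, r = 16, ReLU between, no biases), sums and
applies a sigmoid; the C weights multiply their channels. Spatial
attention then pools the reweighted map over channels (mean and max),
convolves the 2-channel image with a single bias-free 7×7 filter and
applies a sigmoid; the H×W weights multiply all channels. The spatial
operator is computed from the *channel-reweighted* map — the
mathematically consistent reading of the sequential design. Internal
architecture choices (dual pooling, shared bottleneck, reduction 16,
kernel 7) follow the canonical convolutional-block-attention design and
are configurable.

**Implementation.** No deep-learning framework is used: layers,
backpropagation (including through batch-norm statistics, the attention
poolings' argmax routing, and the LSTM recurrence) and Adam are package
R code, with activations kept in a channels-last `(H, W, N, C)` layout
so per-channel reductions and broadcasts vectorize without array
permutations. Every layer's analytic gradient is validated against
central finite differences (relative error below 1e-4, typically 1e-6)
in the test suite. Two details depart from naive textbook training:

* *Batch-norm recalibration.* With small batches, momentum-tracked
  running statistics lag the weights and mis-calibrate eval-mode
  probabilities (rankings — hence AUROC — are unaffected, but
  thresholded accuracy suffers). After early stopping restores the best
  weights, one momentum-free pass over the training set replaces the
  running statistics with their population estimate under those weights.
* *Determinism.* Initialization, shuffling and dropout draw from seeds
  derived from `config$seed` inside a scoped RNG, so training twice with
  one seed is bit-identical and never disturbs the caller's RNG stream.

## Evaluation

`confusion_and_metrics()` counts TP/FP/TN/FN with *abnormal* as the
positive class and derives precision, recall, F1 and accuracy; ratios
with zero denominators are reported as `NA` rather than 0 so aggregates
cannot be silently optimistic. On the published confusion counts
(TP = 233, FP = 2, TN = 238, FN = 7) these formulas give 0.9915, 0.9708,
0.9810 and 0.98125; the package reports the computed accuracy. AUROC
uses the Mann–Whitney rank equivalence with averaged ties and is tested
against an O(N²) concordant-pair oracle and an independent ROC
implementation.

For representation comparison, `compare_feature_types()` draws seeded
normal/abnormal pairs, featurizes both members, and averages PSNR
(`10·log10(MAX²/MSE)`, MAX = 1 for normalized images, +∞ on identical
images) and single-window SSIM (global means, variances, covariance;
C1 = (0.01·MAX)², C2 = (0.03·MAX)²) over pairs, for the mel, MFCC and
fused images. Lower values mean a larger between-class difference. The
published numeric values of this table depend on the private recordings
and are reproduced only as a procedure; the random-pairing rule (the
paper-level protocol does not specify which images are differenced) is a
package choice.

## Problem sizes used by the tests

The defaults above are the full-scale study conditions; the test suite
runs the same code at sizes chosen for a single CPU. Dataset bookkeeping
is verified at full scale (600 + 200 originals through expansion and
splitting). Learning is verified on a scaled-down configuration —
4/8/12 filters, reduction 4, spatial kernel 3 (the canonical small
variant), 24 LSTM units, batch 16, 5 epochs — trained on 200 3–6 s clips
(separation 0.8) with 40 validation and 40 held-out clips, across three
seeds; each run reaches held-out AUROC ≥ 0.95, typically 1.0. The
architecture under test is identical in kind — only widths, kernel and
epochs shrink.

## Known limitations

* The generator's realism is bounded to the qualitative spectral
  contrasts stated above; no claim transfers to clinical audio.
* SSIM is the global single-window variant, appropriate for whole-image
  summary; a sliding-window SSIM is out of scope.
* Training on the full 2,400-recording, 64/128/256-filter configuration
  is CPU-feasible but slow in pure R; the package targets method
  correctness and reproducibility, not throughput.
* Splitting after augmentation permits sibling leakage across subsets
  (see above); this mirrors the published procedure.
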