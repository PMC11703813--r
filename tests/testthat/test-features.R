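test_that("pre-emphasis matches its closed forms", {
  expect_equal(pre_emphasize(c(1, 0, 0)), c(1, -0.97, 0))
  expect_equal(pre_emphasize(rep(0, 5)), rep(0, 5))
  cc <- 0.4
  expect_equal(pre_emphasize(rep(cc, 6)), c(cc, rep(0.03 * cc, 5)))
  rec <- audio_recording(c(1, 0.5, 0.25), 16000)
  out <- pre_emphasize(rec, mu = 0.5)
  expect_s3_class(out, "audio_recording")
  expect_equal(out$samples, c(1, 0, 0))
  expect_error(pre_emphasize(numeric(0)), "empty")
  expect_error(pre_emphasize(c(1, 2), mu = 1), "mu")
})

test_that("pre-emphasis response is 1 - mu at DC and rises with frequency", {
  h <- pre_emphasize(c(1, rep(0, 255)))           # impulse response
  mag <- Mod(stats::fft(h))[1:129]
  expect_equal(mag[1], 0.03, tolerance = 1e-10)
  expect_true(all(diff(mag) > 0))
})

test_that("mel spectrogram has fixed shape across durations", {
  orig <- fixture_originals()
  y <- pre_emphasize(orig$normal)
  m <- compute_mel_spectrogram(y)
  expect_equal(dim(m), c(128L, 128L))
  expect_true(all(is.finite(m)))
  short <- audio_recording(stats::rnorm(3 * 16000, sd = 0.1), 16000)
  expect_equal(dim(compute_mel_spectrogram(short)), c(128L, 128L))
  expect_error(compute_mel_spectrogram(audio_recording(stats::rnorm(100), 16000)),
               "window")
})

test_that("near-silence yields a finite constant-floor mel matrix", {
  quiet <- audio_recording(rep(1e-8, 16000), 16000)
  m <- compute_mel_spectrogram(quiet)
  expect_true(all(is.finite(m)))
})

test_that("a pure tone peaks in the mel band nearest its frequency", {
  f0 <- 1000
  tone <- audio_recording(0.5 * sin(2 * pi * f0 * (0:47999) / 16000), 16000)
  m <- compute_mel_spectrogram(tone)
  centers <- attr(m, "centers_hz")
  peak_band <- which.max(rowMeans(m))
  # independent mel-scale oracle for the expected band
  expected <- which.min(abs(centers - f0))
  expect_lte(abs(peak_band - expected), 1)
})

test_that("MFCC matches a direct DCT-II summation oracle", {
  orig <- fixture_originals()
  y <- pre_emphasize(orig$abnormal)
  cep <- compute_mfcc(y)
  expect_equal(dim(cep), c(13L, 128L))
  # brute-force DCT-II of the log-mel matrix, same resize
  lm <- bruitnet:::log_mel_native(y)
  oracle <- matrix(0, 13, ncol(lm))
  for (k in 0:12) {
    scale <- if (k == 0) sqrt(1 / nrow(lm)) else sqrt(2 / nrow(lm))
    for (j in seq_len(ncol(lm))) {
      oracle[k + 1, j] <- scale *
        sum(lm[, j] * cos(pi / nrow(lm) * ((seq_len(nrow(lm)) - 1) + 0.5) * k))
    }
  }
  oracle <- bruitnet:::resize_time_axis(oracle, 128L)
  expect_lt(max(abs(cep - oracle)), 1e-6)
})

test_that("column normalization maps to [0,1], handles constants, idempotent", {
  expect_equal(normalize_columns(matrix(c(2, 4, 6), 3, 1)),
               matrix(c(0, 0.5, 1), 3, 1))
  expect_equal(normalize_columns(matrix(5, 3, 1)), matrix(0, 3, 1))
  x <- seeded_matrix(20, 10, seed = 4)
  nx <- normalize_columns(x)
  expect_gte(min(nx), 0); expect_lte(max(nx), 1)
  expect_equal(normalize_columns(nx), nx)
  expect_true(all(apply(nx, 2, min) == 0))
  expect_true(all(apply(nx, 2, max) == 1))
  expect_error(normalize_columns(matrix(c(1, Inf), 2, 1)), "finite")
})

test_that("fusion stacks mel rows then MFCC rows", {
  mel <- normalize_columns(seeded_matrix(128, 128, seed = 7))
  mfcc <- normalize_columns(seeded_matrix(13, 128, seed = 8))
  fused <- fuse_features(mel, mfcc)
  expect_equal(dim(fused), c(141L, 128L))
  expect_equal(fused[1:128, ], unclass(mel), ignore_attr = TRUE)
  expect_equal(fused[129, ], mfcc[1, ], ignore_attr = TRUE)
  expect_equal(fused[141, ], mfcc[13, ], ignore_attr = TRUE)
  expect_error(fuse_features(mel, mfcc[, 1:64]), "time axis")
})

test_that("finalize re-normalizes, transposes and adds the channel axis", {
  fused <- fuse_features(normalize_columns(seeded_matrix(128, 128, seed = 2)),
                         normalize_columns(seeded_matrix(13, 128, seed = 3)))
  ff <- finalize_features(fused)
  expect_equal(dim(ff), c(128L, 141L, 1L))
  expect_gte(min(ff), 0); expect_lte(max(ff), 1)
  # idempotent fixed point (ignoring the channel axis)
  again <- finalize_features(t(ff[, , 1]))
  expect_equal(again, ff, ignore_attr = TRUE)
})

test_that("featurize is total over 3-21 s clips and deterministic", {
  orig <- fixture_originals()
  clips <- clip_segments(orig$normal, seed = 77)
  f_short <- featurize(clips[[1]])
  f_long <- featurize(clips[[2]])
  expect_equal(dim(f_short), c(128L, 141L, 1L))
  expect_equal(dim(f_long), c(128L, 141L, 1L))
  expect_gte(min(f_short), 0); expect_lte(max(f_short), 1)
  expect_identical(featurize(clips[[1]]), f_short)
})
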