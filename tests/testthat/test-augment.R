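test_that("add_white_noise hits the requested SNR", {
  x <- sin(2 * pi * 440 * (0:47999) / 16000)  # unit-amplitude sine, RMS 1/sqrt(2)
  rec <- audio_recording(x, 16000, id = "s")
  noisy <- add_white_noise(rec, snr_db = 20, seed = 3)
  resid <- noisy$samples - x
  snr_est <- 10 * log10(mean(x^2) / mean(resid^2))
  expect_equal(snr_est, 20, tolerance = 0.005)      # within 0.1 dB
  # noise RMS should be signal RMS / 10 at 20 dB
  expect_equal(sqrt(mean(resid^2)), sqrt(mean(x^2)) / 10, tolerance = 0.01)
  expect_equal(noisy$provenance, "noise_augmented")
  expect_identical(add_white_noise(rec, 20, seed = 3)$samples, noisy$samples)
})

test_that("very high SNR approaches the identity", {
  rec <- audio_recording(stats::rnorm(16000, sd = 0.2), 16000)
  out <- add_white_noise(rec, snr_db = 100, seed = 1)
  expect_lt(max(abs(out$samples - rec$samples)), 1e-4)
})

test_that("silent input raises a degenerate-input error", {
  rec <- audio_recording(rep(0, 1000) + 0, 16000)
  rec$samples <- rep(0, 1000)
  expect_error(add_white_noise(rec, 20, seed = 1), "silent|zero-power")
})

test_that("clip_segments produces in-range contiguous sub-intervals", {
  rec <- generate_bruit(bruit_params("normal", duration = 30, seed = 5))
  clips <- clip_segments(rec, seed = 9)
  d1 <- duration(clips[[1]]); d2 <- duration(clips[[2]])
  expect_gte(d1, 3); expect_lte(d1, 6)
  expect_gte(d2, 18); expect_lte(d2, 21)
  expect_equal(clips[[1]]$provenance, "clip_3_6")
  expect_equal(clips[[2]]$provenance, "clip_18_21")
  expect_equal(clips[[1]]$label, rec$label)
  # each clip is a contiguous sub-array of the source
  for (cl in clips) {
    hit <- which(abs(rec$samples - cl$samples[1]) < 1e-15)
    found <- any(vapply(hit, function(i0) {
      i1 <- i0 + length(cl$samples) - 1L
      i1 <= length(rec$samples) &&
        identical(rec$samples[i0:i1], cl$samples)
    }, logical(1)))
    expect_true(found)
  }
})

test_that("clip_segments enforces the 21 s precondition", {
  short <- audio_recording(stats::rnorm(10 * 16000), 16000)
  expect_error(clip_segments(short, seed = 1), "21")
  # a 24 s input still admits the long clip (start offset bounded)
  rec24 <- generate_bruit(bruit_params("normal", duration = 24, seed = 6))
  clips <- clip_segments(rec24, seed = 2)
  expect_lte(duration(clips[[2]]), 21)
  start_max <- duration(rec24) - duration(clips[[2]])
  expect_lte(start_max, 6)
})

test_that("expand_and_balance applies the 2x/6x multiplicities", {
  ds <- generate_dataset(1, 1, seed = 31)
  ex <- expand_and_balance(ds, snr_db = 20, seed = 5)
  expect_equal(nrow(ex), 8)                         # 2 + 6
  expect_equal(sum(ex$label == "normal"), 2)
  expect_equal(sum(ex$label == "abnormal"), 6)
  expect_false(any(duplicated(ex$id)))
  expect_true(all(!is.na(ex$parent_id)))
  # labels conserved relative to parents
  parents <- stats::setNames(ds$label, ds$id)
  roots <- ifelse(ex$parent_id %in% names(parents), ex$parent_id, NA)
  expect_true(all(is.na(roots) | ex$label == parents[roots]))
})

test_that("expand_and_balance balances 3:1 inputs", {
  ds <- generate_dataset(3, 1, seed = 41)
  ex <- expand_and_balance(ds, seed = 6)
  expect_equal(sum(ex$label == "normal"), 6)
  expect_equal(sum(ex$label == "abnormal"), 6)
  expect_error(expand_and_balance(generate_dataset(2, 0, seed = 1)),
               "both classes")
})

test_that("split_dataset reproduces stratified floor rounding", {
  # 10 recordings (5 + 5) -> 7 / 1 / 2 with class imbalance <= 1 per subset
  ds <- generate_dataset(0, 0)
  man <- tibble::tibble(
    id = sprintf("r%02d", 1:10),
    label = rep(c("normal", "abnormal"), each = 5),
    provenance = "original", parent_id = NA_character_,
    duration = 24, rate = 16000,
    rec = replicate(10, audio_recording(stats::rnorm(100), 16000),
                    simplify = FALSE)
  )
  sp <- split_dataset(man, seed = 3)
  expect_equal(nrow(sp$train), 7)
  expect_equal(nrow(sp$validation), 1)
  expect_equal(nrow(sp$test), 2)
  for (part in list(sp$train, sp$validation, sp$test)) {
    tab <- table(factor(part$label, levels = c("normal", "abnormal")))
    expect_lte(abs(tab[1] - tab[2]), 1)
  }
  # disjoint by id, and deterministic given the seed
  ids <- c(sp$train$id, sp$validation$id, sp$test$id)
  expect_false(any(duplicated(ids)))
  sp2 <- split_dataset(man, seed = 3)
  expect_identical(sp$test$id, sp2$test$id)
  expect_error(split_dataset(man[0, ], seed = 1), "empty")
})

test_that("split sizes stay within one of the exact ratios", {
  for (n_n in c(8, 13)) {
    ds <- tibble::tibble(
      id = sprintf("x%02d", seq_len(2 * n_n)),
      label = rep(c("normal", "abnormal"), each = n_n),
      rec = replicate(2 * n_n, audio_recording(stats::rnorm(50), 16000),
                      simplify = FALSE)
    )
    sp <- split_dataset(ds, seed = 11)
    n <- 2 * n_n
    expect_lte(abs(nrow(sp$validation) - 0.1 * n), 1)
    expect_lte(abs(nrow(sp$test) - 0.2 * n), 1)
    expect_equal(nrow(sp$train) + nrow(sp$validation) + nrow(sp$test), n)
  }
})
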