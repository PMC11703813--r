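# Lazily built, memoized fixtures shared across test files. Everything is
# generated in code under fixed seeds; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) {
    assign(key, force(expr), envir = .fixtures)
  }
  get(key, envir = .fixtures)
}

# A pair of full-length originals (one per class), 24 s, separation 0.8.
fixture_originals <- function() {
  memo("originals", list(
    normal = generate_bruit(bruit_params("normal", duration = 24, seed = 301)),
    abnormal = generate_bruit(bruit_params("abnormal", duration = 24,
                                           separation = 0.8, seed = 302))
  ))
}

# Short 3-6 s clips cut from seeded 24 s bruits: two clips per original,
# n_per_class originals per class. Returns list(clips, labels).
fixture_clips <- function(n_per_class = 70, separation = 0.8, seed = 101) {
  memo(sprintf("clips_%d_%g_%d", n_per_class, separation, seed), {
    ds <- generate_dataset(n_per_class, n_per_class,
                           params = bruit_params(separation = separation),
                           seed = seed)
    clips <- vector("list", 2L * nrow(ds))
    labels <- character(2L * nrow(ds))
    k <- 0L
    for (i in seq_len(nrow(ds))) {
      for (j in 1:2) {
        k <- k + 1L
        clips[[k]] <- clip_segments(ds$rec[[i]], seed = seed + 977L * i + j)[[1]]
        labels[k] <- clips[[k]]$label
      }
    }
    list(clips = clips, labels = labels)
  })
}

fixture_features <- function() {
  memo("features", {
    dat <- fixture_clips()
    list(features = lapply(dat$clips, featurize), labels = dat$labels)
  })
}

# Reduced-size CBAM-LSTM configuration used by the learning tests (the
# default configuration keeps the full-scale published values).
small_config <- function(seed) {
  model_config(conv_filters = c(4L, 8L, 12L), cbam_reduction = 4L,
               cbam_kernel = 3L, lstm_units = 24L, dense_units = 16L,
               dropout_rate = 0.3, batch_size = 16L, max_epochs = 5L,
               early_stop_patience = 5L, seed = seed)
}

# One full scaled-down training run: 200 train / 40 validation / 40 test
# clips at separation 0.8. Memoized per seed.
fixture_trained_run <- function(seed) {
  memo(sprintf("trained_%d", seed), {
    dat <- fixture_features()
    idx <- with(list(), {
      set.seed(500 + seed)
      sample(length(dat$features))
    })
    tr <- idx[1:200]; va <- idx[201:240]; te <- idx[241:280]
    model <- build_model(small_config(seed))
    model <- train_model(model, dat$features[tr], dat$labels[tr],
                         dat$features[va], dat$labels[va])
    pred <- predict(model, dat$features[te])
    list(model = model, trace = model$trace,
         test_labels = dat$labels[te], probabilities = pred$probability,
         auroc = roc_auc(dat$labels[te], pred$probability)$auroc)
  })
}

# Deterministic pseudo-random test matrix.
seeded_matrix <- function(nr, nc, seed = 1) {
  set.seed(seed)
  matrix(stats::rnorm(nr * nc), nr, nc)
}

# Write a WAV with arbitrary rate/channels/bit depth for loader tests.
write_test_wav <- function(path, data, rate, bits = 16L) {
  ch <- if (is.matrix(data)) ncol(data) else 1L
  frames <- if (is.matrix(data)) nrow(data) else length(data)
  inter <- if (is.matrix(data)) as.vector(t(data)) else data
  con <- file(path, "wb")
  on.exit(close(con))
  bytes_per <- bits %/% 8L
  data_bytes <- frames * ch * bytes_per
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(if (bits == 32L) 3L else 1L, con, size = 2, endian = "little")
  writeBin(as.integer(ch), con, size = 2, endian = "little")
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * ch * bytes_per), con, size = 4, endian = "little")
  writeBin(as.integer(ch * bytes_per), con, size = 2, endian = "little")
  writeBin(as.integer(bits), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_bytes), con, size = 4, endian = "little")
  if (bits == 16L) {
    writeBin(as.integer(round(pmax(-1, pmin(1, inter)) * 32767)), con,
             size = 2, endian = "little")
  } else {
    writeBin(inter, con, size = 4, endian = "little")
  }
  invisible(path)
}
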