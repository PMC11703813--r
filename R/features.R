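#' Pre-emphasis filter
#'
#' First-order high-pass filter `y[n] = x[n] - mu * x[n-1]` (with
#' `y[1] = x[1]`), boosting high-frequency components before spectral
#' analysis. The default aggravation coefficient is `mu = 0.97`.
#'
#' @param rec An [audio_recording()] or a numeric vector.
#' @param mu Pre-emphasis coefficient, `0 <= mu < 1`.
#' @return Same type as the input, filtered; length preserved.
#' @export
pre_emphasize <- function(rec, mu = 0.97) {
  if (!is.numeric(mu) || mu < 0 || mu >= 1) {
    stop("mu must satisfy 0 <= mu < 1", call. = FALSE)
  }
  x <- if (inherits(rec, "audio_recording")) rec$samples else as.numeric(rec)
  if (length(x) == 0L) stop("empty input to pre_emphasize", call. = FALSE)
  y <- x - mu * c(0, x[-length(x)])
  if (inherits(rec, "audio_recording")) {
    out <- rec
    out$samples <- y
    out
  } else {
    y
  }
}

# HTK mel scale
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Mel filter bank
#'
#' Triangular filters on the HTK mel scale (`2595 * log10(1 + f/700)`),
#' mapping an STFT power spectrum of `n_fft/2 + 1` bins to `n_mels` bands.
#'
#' @param n_mels Number of mel bands.
#' @param n_fft FFT length in samples.
#' @param rate Sampling rate (Hz).
#' @param fmin,fmax Band-edge frequencies (Hz); `fmax` defaults to Nyquist.
#' @return `n_mels x (n_fft/2 + 1)` filter matrix, plus band center
#'   frequencies in attribute `"centers_hz"`.
#' @export
mel_filterbank <- function(n_mels = 128, n_fft = 512, rate = 16000,
                           fmin = 0, fmax = rate / 2) {
  n_bins <- n_fft %/% 2 + 1
  freqs <- seq(0, rate / 2, length.out = n_bins)
  mel_pts <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz_pts <- mel_to_hz(mel_pts)
  fb <- matrix(0, n_mels, n_bins)
  for (m in seq_len(n_mels)) {
    lo <- hz_pts[m]; ce <- hz_pts[m + 1]; hi <- hz_pts[m + 2]
    up <- (freqs - lo) / (ce - lo)
    down <- (hi - freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, down))
  }
  attr(fb, "centers_hz") <- hz_pts[2:(n_mels + 1)]
  fb
}

# Short-time power spectrum: 25 ms Hann window, 10 ms hop, no padding.
# Returns (n_fft/2 + 1) x n_frames matrix of |STFT|^2.
stft_power <- function(x, rate, win_sec = 0.025, hop_sec = 0.010,
                       n_fft = NULL) {
  win_len <- round(win_sec * rate)
  hop <- round(hop_sec * rate)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(win_len))
  n <- length(x)
  if (n < win_len) {
    stop("recording shorter than one analysis window (",
         sprintf("%.0f ms", 1000 * win_sec), ")", call. = FALSE)
  }
  n_frames <- (n - win_len) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(win_len), starts, "+")
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win_len) - 1) / win_len)  # periodic Hann
  frames <- matrix(x[idx], nrow = win_len) * win
  if (n_fft > win_len) {
    frames <- rbind(frames, matrix(0, n_fft - win_len, n_frames))
  }
  sp <- stats::mvfft(frames)[seq_len(n_fft %/% 2 + 1), , drop = FALSE]
  Mod(sp)^2
}

# Resize the columns (time frames) of a matrix to n_out by linear
# interpolation along time.
resize_time_axis <- function(m, n_out = 128L) {
  n_in <- ncol(m)
  if (n_in == n_out) return(m)
  if (n_in == 1L) return(m[, rep(1L, n_out), drop = FALSE])
  pos <- seq(1, n_in, length.out = n_out)
  lo <- floor(pos); hi <- pmin(lo + 1L, n_in); w <- pos - lo
  m[, lo, drop = FALSE] * rep(1 - w, each = nrow(m)) +
    m[, hi, drop = FALSE] * rep(w, each = nrow(m))
}

LOG_POWER_FLOOR <- 1e-10

#' Log-power Mel spectrogram at fixed (128, 128) resolution
#'
#' STFT with a 25 ms Hann window and 10 ms hop at 16 kHz (400-sample
#' window, 160-sample hop), a 128-band mel filter bank, `10*log10`
#' compression (power floored at 1e-10), and linear interpolation of the
#' time axis to 128 frames.
#'
#' @param rec A pre-emphasized [audio_recording()] (or numeric vector at
#'   `rate`).
#' @param rate Sampling rate; taken from `rec` when it is a recording.
#' @param n_mels Number of mel bands (and output rows), default 128.
#' @param n_frames Output time frames (columns), default 128.
#' @return `n_mels x n_frames` matrix (rows = mel bands, columns = time).
#' @export
compute_mel_spectrogram <- function(rec, rate = 16000, n_mels = 128L,
                                    n_frames = 128L) {
  lm <- log_mel_native(rec, rate, n_mels)
  out <- resize_time_axis(lm, n_frames)
  attr(out, "centers_hz") <- attr(lm, "centers_hz")
  out
}

# Log-mel matrix at native frame resolution (shared by the mel and MFCC
# paths so the STFT is computed once).
log_mel_native <- function(rec, rate = 16000, n_mels = 128L) {
  x <- if (inherits(rec, "audio_recording")) rec$samples else as.numeric(rec)
  if (inherits(rec, "audio_recording")) rate <- rec$rate
  pw <- stft_power(x, rate)
  fb <- mel_filterbank(n_mels = n_mels, n_fft = 2L * (nrow(pw) - 1L),
                       rate = rate)
  lm <- 10 * log10(pmax(fb %*% pw, LOG_POWER_FLOOR))
  attr(lm, "centers_hz") <- attr(fb, "centers_hz")
  lm
}

# Orthonormal DCT-II matrix (n_out x n_in), rows are basis functions.
dct_matrix <- function(n_out, n_in) {
  k <- seq_len(n_out) - 1
  n <- seq_len(n_in) - 1
  m <- sqrt(2 / n_in) * cos(outer(k, n + 0.5) * pi / n_in)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' MFCC matrix at fixed (13, 128) resolution
#'
#' Same framing as [compute_mel_spectrogram()]; per frame, the 128-band
#' log-mel powers are transformed by an orthonormal DCT-II and the lowest
#' 13 coefficients (including the 0th) are kept; the time axis is then
#' resized to 128 frames.
#'
#' @param rec A pre-emphasized [audio_recording()] (or numeric vector).
#' @param rate Sampling rate; taken from `rec` when it is a recording.
#' @param n_mfcc Number of cepstral coefficients (rows), default 13.
#' @param n_mels Mel bands feeding the DCT, default 128.
#' @param n_frames Output time frames (columns), default 128.
#' @return `n_mfcc x n_frames` matrix (rows = coefficients, columns = time).
#' @export
compute_mfcc <- function(rec, rate = 16000, n_mfcc = 13L, n_mels = 128L,
                         n_frames = 128L) {
  logmel <- log_mel_native(rec, rate, n_mels)
  cep <- dct_matrix(n_mfcc, n_mels) %*% logmel
  resize_time_axis(cep, n_frames)
}

#' Column-wise min-max normalization to \[0, 1\]
#'
#' Maps each column `j` by `(v - min(col_j)) / (max(col_j) - min(col_j))`.
#' Constant columns (zero range) map to all-zeros, which keeps the output
#' range invariant.
#'
#' @param m A finite numeric matrix (columns index time frames).
#' @return Matrix of the same shape with all values in \[0, 1\].
#' @export
normalize_columns <- function(m) {
  m <- as.matrix(m)
  if (!all(is.finite(m))) stop("non-finite values in matrix", call. = FALSE)
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  rng <- hi - lo
  out <- sweep(m, 2, lo, "-")
  nz <- rng > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, rng[nz], "/")
  out[, !nz] <- 0
  out
}

#' Fuse normalized Mel and MFCC matrices along the feature axis
#'
#' Stacks the 128 mel rows and the 13 cepstral rows into a single
#' (141, 128) matrix: rows 1-128 are the mel bands, rows 129-141 the
#' MFCCs.
#'
#' @param mel_norm Normalized `128 x 128` mel matrix.
#' @param mfcc_norm Normalized `13 x 128` MFCC matrix.
#' @return `141 x 128` fused matrix.
#' @export
fuse_features <- function(mel_norm, mfcc_norm) {
  if (ncol(mel_norm) != ncol(mfcc_norm)) {
    stop("mel and MFCC matrices must share the time axis (columns)",
         call. = FALSE)
  }
  rbind(unclass(mel_norm), unclass(mfcc_norm))
}

#' Final normalization and model-input shaping
#'
#' Re-normalizes the fused matrix column-wise (so the fused feature
#' dimensions share one scale), transposes to (time, feature) and appends
#' a singleton channel axis, yielding the network input of shape
#' `(time = 128, feature = 141, channel = 1)`.
#'
#' @param fused `141 x 128` fused matrix from [fuse_features()].
#' @return A 3-d array of dim `(128, 141, 1)` with values in \[0, 1\].
#' @export
finalize_features <- function(fused) {
  f2 <- normalize_columns(fused)
  out <- array(t(f2), dim = c(ncol(f2), nrow(f2), 1L))
  class(out) <- c("fused_feature", class(out))
  out
}

#' Full feature-fusion front end
#'
#' Composition of [pre_emphasize()], [compute_mel_spectrogram()],
#' [compute_mfcc()], [normalize_columns()], [fuse_features()] and
#' [finalize_features()]: from a waveform of any duration from 3 s to
#' 30 s to the fixed `(128, 141, 1)` network input.
#'
#' @param rec An [audio_recording()].
#' @param mu Pre-emphasis coefficient, default 0.97.
#' @return A `fused_feature` array of dim `(128, 141, 1)`.
#' @export
featurize <- function(rec, mu = 0.97) {
  stopifnot(inherits(rec, "audio_recording"))
  y <- pre_emphasize(rec, mu = mu)
  lm <- log_mel_native(y)
  mel <- normalize_columns(resize_time_axis(lm, 128L))
  mfcc <- normalize_columns(resize_time_axis(dct_matrix(13L, nrow(lm)) %*% lm,
                                             128L))
  finalize_features(fuse_features(mel, mfcc))
}

#' Featurize every recording in a manifest
#'
#' @param manifest Manifest tibble with list-column `rec` (or list of
#'   recordings).
#' @param mu Pre-emphasis coefficient.
#' @return The manifest tibble with a `feature` list-column of
#'   `(128, 141, 1)` arrays.
#' @export
featurize_dataset <- function(manifest, mu = 0.97) {
  if (!tibble::is_tibble(manifest)) manifest <- recs_to_manifest(manifest)
  manifest$feature <- lapply(manifest$rec, featurize, mu = mu)
  manifest
}
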