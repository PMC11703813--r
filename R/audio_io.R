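#' Labelled mono audio recording
#'
#' Container for a mono waveform together with its sampling rate, class
#' label and provenance. Amplitudes are dimensionless and expected to lie
#' in \[-1, 1\]; the pipeline's ingestion convention is 16 kHz mono.
#'
#' @param samples Numeric vector of amplitudes in \[-1, 1\].
#' @param rate Sampling rate in Hz.
#' @param label Class label, `"normal"` or `"abnormal"`.
#' @param id Identifier string.
#' @param provenance One of `"original"`, `"noise_augmented"`,
#'   `"clip_3_6"`, `"clip_18_21"`.
#' @return An object of class `audio_recording`.
#' @export
audio_recording <- function(samples, rate, label = c("normal", "abnormal"),
                            id = "rec", provenance = "original") {
  label <- match.arg(label)
  provenance <- match.arg(provenance,
                          c("original", "noise_augmented", "clip_3_6", "clip_18_21"))
  samples <- as.numeric(samples)
  if (length(samples) == 0L) {
    stop("empty audio: an audio_recording needs at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("non-finite samples in audio_recording", call. = FALSE)
  }
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("rate must be a single positive number (Hz)", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = as.numeric(rate), label = label,
         id = as.character(id), provenance = provenance),
    class = "audio_recording"
  )
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording %s> %s/%s: %.2f s @ %g Hz (%d samples)\n",
              x$id, x$label, x$provenance, duration(x), x$rate,
              length(x$samples)))
  invisible(x)
}

#' Duration of a recording in seconds
#'
#' @param rec An `audio_recording`.
#' @return Duration in seconds.
#' @export
duration <- function(rec) length(rec$samples) / rec$rate

#' Read a WAV file as a mono recording at a target rate
#'
#' Reads a RIFF/WAVE file (16-bit PCM, 32-bit float; 24-bit PCM also
#' accepted), averages channels to mono, resamples to `target_rate` in the
#' frequency domain when the native rate differs, and rescales so the peak
#' amplitude is at most 1.
#'
#' @param path Path to a WAV file.
#' @param target_rate Desired sampling rate in Hz (default 16000, the
#'   pipeline convention).
#' @param label,id,provenance Metadata attached to the result; `id`
#'   defaults to the file name without extension.
#' @return An [audio_recording()].
#' @export
load_wav <- function(path, target_rate = 16000, label = "normal",
                     id = NULL, provenance = "original") {
  w <- read_wav_raw(path)
  if (ncol(w$data) > 1L) {
    x <- rowMeans(w$data)
  } else {
    x <- w$data[, 1L]
  }
  if (length(x) == 0L) stop("empty WAV file: ", path, call. = FALSE)
  if (w$rate != target_rate) {
    x <- resample_fft(x, target_rate, w$rate)
  }
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  if (is.null(id)) id <- sub("\\.[Ww][Aa][Vv]$", "", basename(path))
  audio_recording(x, target_rate, label = label, id = id,
                  provenance = provenance)
}

#' Write a recording to a 16-bit PCM WAV file
#'
#' Always writes 16-bit PCM mono. Label, id and provenance are not stored
#' in the WAV container (RIFF has no label field); use
#' [write_manifest()] to carry them alongside.
#'
#' @param rec An [audio_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_wav <- function(rec, path) {
  stopifnot(inherits(rec, "audio_recording"))
  x <- pmax(-1, pmin(1, rec$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n <- length(pcm)
  data_bytes <- 2L * n
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rec$rate), con, size = 4, endian = "little")
  writeBin(as.integer(rec$rate * 2), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")           # block align
  writeBin(16L, con, size = 2, endian = "little")          # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# Minimal RIFF/WAVE chunk walker. Returns list(rate, data) with data a
# frames x channels numeric matrix scaled to [-1, 1].
read_wav_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  readBin(con, "integer", 1, size = 4, endian = "little")
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(wave, "WAVE")) stop("not a RIFF/WAVE file: ", path, call. = FALSE)
  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1, size = 4, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      fmt_bytes <- readBin(con, "raw", size)
      fmt <- list(
        code = readBin(fmt_bytes[1:2], "integer", 1, size = 2, endian = "little"),
        channels = readBin(fmt_bytes[3:4], "integer", 1, size = 2, endian = "little"),
        rate = readBin(fmt_bytes[5:8], "integer", 1, size = 4, endian = "little"),
        bits = readBin(fmt_bytes[15:16], "integer", 1, size = 2, endian = "little")
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + (size %% 2L))
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop("corrupt WAV (missing fmt or data chunk): ", path, call. = FALSE)
  }
  # WAVE_FORMAT_EXTENSIBLE (0xFFFE) carries the real code in the extension;
  # treat by bit depth like the common cases.
  # integer PCM is decoded with the same positive full-scale constant the
  # writer uses, so a write/read cycle is an identity up to rounding
  x <- switch(
    as.character(fmt$bits),
    "16" = readBin(data_raw, "integer", length(data_raw) / 2, size = 2,
                   signed = TRUE, endian = "little") / 32767,
    "32" = if (fmt$code == 3L) {
      readBin(data_raw, "double", length(data_raw) / 4, size = 4,
              endian = "little")
    } else {
      readBin(data_raw, "integer", length(data_raw) / 4, size = 4,
              endian = "little") / 2147483647
    },
    "24" = read_pcm24(data_raw),
    stop("unsupported WAV bit depth: ", fmt$bits, call. = FALSE)
  )
  if (length(x) == 0L) stop("empty WAV file: ", path, call. = FALSE)
  ch <- max(1L, fmt$channels)
  n <- (length(x) %/% ch) * ch
  list(rate = fmt$rate, data = matrix(x[seq_len(n)], ncol = ch, byrow = TRUE))
}

read_pcm24 <- function(raw) {
  n <- length(raw) %/% 3L
  b <- matrix(as.integer(raw[seq_len(3L * n)]), nrow = 3L)
  v <- b[1, ] + 256L * b[2, ] + 65536L * b[3, ]
  v <- ifelse(v >= 8388608, v - 16777216, v)
  v / 8388607
}

# Sample-rate conversion in the frequency domain: the spectrum is
# truncated (downsampling) or zero-extended (upsampling) at a
# length-scaled bin count, which preserves passband gain exactly for
# band-limited content. Input is zero-padded to a 2-3-5-smooth FFT
# length; ringing is confined to the signal edges.
resample_fft <- function(x, target_rate, native_rate) {
  n <- length(x)
  out_n <- round(n * target_rate / native_rate)
  if (out_n == n) return(x)
  nfft <- stats::nextn(n, c(2L, 3L, 5L))
  X <- stats::fft(c(x, numeric(nfft - n)))
  m_out <- round(nfft * target_rate / native_rate)
  keep <- min(nfft, m_out) %/% 2L
  Y <- complex(real = numeric(m_out), imaginary = numeric(m_out))
  Y[1:(keep + 1L)] <- X[1:(keep + 1L)]
  if (keep > 1L) {
    Y[m_out - (1:(keep - 1L)) + 1L] <- X[nfft - (1:(keep - 1L)) + 1L]
  }
  y <- Re(stats::fft(Y, inverse = TRUE)) / nfft
  y[seq_len(out_n)]
}

#' Write a dataset manifest
#'
#' Writes the sidecar metadata CSV (`id,path,label,provenance,parent_id`)
#' that carries labels for a directory of WAV files.
#'
#' @param manifest A tibble with at least columns `id`, `path`, `label`,
#'   `provenance`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  keep <- intersect(c("id", "path", "label", "provenance", "parent_id", "split"),
                    names(manifest))
  utils::write.csv(as.data.frame(manifest[, keep]), path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Manifest CSV path.
#' @return A tibble with the manifest columns.
#' @export
read_manifest <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
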