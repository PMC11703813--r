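#' Parameters of the synthetic bruit generator
#'
#' Describes one synthetic arteriovenous-fistula (AVF) shunt sound. The
#' generator emulates the qualitative class contrast of real bruits:
#' normal recordings carry relatively uniform low-passed turbulence energy,
#' while abnormal (stenotic) recordings have lower overall spectral energy,
#' a narrower turbulence band, and intermittent narrowband bursts.
#'
#' @param label `"normal"` or `"abnormal"`.
#' @param duration Recording length in seconds, within \[24, 30\].
#' @param rate Sampling rate in Hz (16000 by convention).
#' @param heart_rate Beats per second driving the systolic pulse train
#'   (default 1.2, i.e. 72 bpm).
#' @param separation Effect-size knob in \[0, 1\]: 0 makes both classes
#'   draws from the same distribution, larger values increase the
#'   normal/abnormal spectral contrast.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `bruit_params` list.
#' @export
bruit_params <- function(label = c("normal", "abnormal"), duration = 27,
                         rate = 16000, heart_rate = 1.2, separation = 0.8,
                         seed = 1L) {
  label <- match.arg(label)
  if (!is.numeric(duration) || duration < 24 || duration > 30) {
    stop("duration must lie in [24, 30] seconds", call. = FALSE)
  }
  if (!is.numeric(separation) || separation < 0 || separation > 1) {
    stop("separation must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(heart_rate) || heart_rate <= 0) {
    stop("heart_rate must be positive (beats per second)", call. = FALSE)
  }
  structure(list(label = label, duration = duration, rate = rate,
                 heart_rate = heart_rate, separation = separation,
                 seed = as.integer(seed)),
            class = "bruit_params")
}

#' Generate one synthetic AVF shunt sound
#'
#' Produces a seeded, deterministic bruit-like waveform: low-passed
#' Gaussian turbulence amplitude-modulated by a Gaussian-windowed pulse
#' train at the heart rate. For `label = "abnormal"` the waveform is
#' attenuated by `1 - 0.5 * separation`, the turbulence low-pass corner is
#' narrowed, and randomized narrowband high-frequency bursts are
#' superimposed, so that for `separation > 0` mean spectral power of the
#' abnormal class is below the normal class.
#'
#' @param params A [bruit_params()] object.
#' @return An [audio_recording()] with peak amplitude at most 1.
#' @export
generate_bruit <- function(params) {
  stopifnot(inherits(params, "bruit_params"))
  p <- params
  with_seed(p$seed, {
    n <- round(p$duration * p$rate)
    abnormal <- p$label == "abnormal"
    atten <- if (abnormal) 1 - 0.5 * p$separation else 1
    corner <- if (abnormal) 2000 * (1 - 0.6 * p$separation) else 2000

    bf <- signal::butter(2, corner / (p$rate / 2), type = "low")
    turb <- iir_filter(bf, stats::rnorm(n))
    turb <- turb / stats::sd(turb)

    # systolic amplitude modulation: Gaussian bump per beat over a baseline
    env <- rep(0.35, n)
    period <- 1 / p$heart_rate
    centers <- seq(period / 2, p$duration, by = period)
    centers <- centers + stats::rnorm(length(centers), sd = 0.01)
    sigma <- 0.045
    half <- round(4 * sigma * p$rate)
    tt <- (-half:half) / p$rate
    bump <- 1.6 * exp(-tt^2 / (2 * sigma^2))
    for (c0 in centers) {
      i0 <- round(c0 * p$rate)
      idx <- (i0 - half):(i0 + half)
      keep <- idx >= 1L & idx <= n
      env[idx[keep]] <- env[idx[keep]] + bump[keep]
    }
    x <- atten * turb * env

    # intermittent narrowband bursts (stenotic jet tones), abnormal only
    n_burst <- stats::rpois(1, lambda = 1.5 * p$duration)
    b_centers <- stats::runif(n_burst, 0, p$duration)
    b_freqs <- stats::runif(n_burst, 2500, 6000)
    b_phases <- stats::runif(n_burst, 0, 2 * pi)
    if (abnormal && p$separation > 0 && n_burst > 0) {
      bsig <- 0.02
      bhalf <- round(4 * bsig * p$rate)
      bt <- (-bhalf:bhalf) / p$rate
      for (k in seq_len(n_burst)) {
        i0 <- round(b_centers[k] * p$rate)
        idx <- (i0 - bhalf):(i0 + bhalf)
        keep <- idx >= 1L & idx <= n
        tone <- 0.45 * p$separation *
          exp(-bt^2 / (2 * bsig^2)) * sin(2 * pi * b_freqs[k] * bt + b_phases[k])
        x[idx[keep]] <- x[idx[keep]] + tone[keep]
      }
    }

    # gain chosen so the peak-safety clamp below stays inactive for
    # ordinary draws of either class (a data-dependent rescale would
    # distort the between-class energy contrast)
    x <- 0.09 * x
    peak <- max(abs(x))
    if (peak > 0.999) x <- x * (0.999 / peak)
    audio_recording(x, p$rate, label = p$label,
                    id = sprintf("%s_%08d", p$label, p$seed %% 100000000L),
                    provenance = "original")
  })
}

#' Generate a labelled synthetic bruit dataset
#'
#' Draws per-recording durations uniformly in \[24, 30\] s and derives one
#' child seed per recording, then calls [generate_bruit()]. The result is
#' a manifest tibble with the waveforms in a list-column, mirroring the
#' 600 normal / 200 abnormal composition of a clinical AVF sound archive
#' when called with those counts.
#'
#' @param n_normal,n_abnormal Recording counts per class (>= 0).
#' @param params Template [bruit_params()]; `label`, `duration` and `seed`
#'   are overridden per recording.
#' @param seed Integer master seed for durations and child seeds.
#' @return A tibble with columns `id`, `label`, `provenance`, `parent_id`,
#'   `duration`, `rate`, `seed` and list-column `rec`.
#' @export
generate_dataset <- function(n_normal, n_abnormal,
                             params = bruit_params(), seed = 1L) {
  stopifnot(n_normal >= 0, n_abnormal >= 0)
  n <- n_normal + n_abnormal
  labels <- rep(c("normal", "abnormal"), c(n_normal, n_abnormal))
  if (n == 0L) {
    return(tibble::tibble(id = character(), label = character(),
                          provenance = character(), parent_id = character(),
                          duration = numeric(), rate = numeric(),
                          seed = integer(), rec = list()))
  }
  seeds <- derive_seeds(seed, n)
  durations <- with_seed(seed + 1L, stats::runif(n, 24, 30))
  recs <- vector("list", n)
  ids <- character(n)
  for (i in seq_len(n)) {
    pi <- bruit_params(label = labels[i], duration = durations[i],
                       rate = params$rate, heart_rate = params$heart_rate,
                       separation = params$separation, seed = seeds[i])
    recs[[i]] <- generate_bruit(pi)
    ids[i] <- sprintf("%s_%04d", labels[i], i)
    recs[[i]]$id <- ids[i]
  }
  tibble::tibble(id = ids, label = labels, provenance = "original",
                 parent_id = NA_character_, duration = durations,
                 rate = params$rate, seed = seeds, rec = recs)
}

#' Mean band power of a recording
#'
#' Mean squared amplitude of the waveform band-limited to `band` (Hz),
#' estimated with a 4th-order Butterworth filter. Used as the scalar
#' statistic behind the band-power threshold classifier in separability
#' checks.
#'
#' @param rec An [audio_recording()].
#' @param band Length-2 numeric, band edges in Hz; a lower edge of 0 gives
#'   a low-pass band.
#' @return Mean band power (dimensionless).
#' @export
band_power <- function(rec, band = c(0, 2000)) {
  stopifnot(inherits(rec, "audio_recording"), length(band) == 2)
  nyq <- rec$rate / 2
  f <- if (band[1] <= 0) {
    signal::butter(4, band[2] / nyq, type = "low")
  } else {
    signal::butter(4, band / nyq, type = "pass")
  }
  y <- iir_filter(f, rec$samples)
  mean(y^2)
}
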