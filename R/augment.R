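#' Add white noise at a prescribed signal-to-noise ratio
#'
#' Adds seeded Gaussian white noise scaled so that
#' `10 * log10(P_signal / P_noise) = snr_db`, simulating background
#' interference during auscultation.
#'
#' @param rec An [audio_recording()].
#' @param snr_db Target signal-to-noise ratio in dB (finite).
#' @param seed Integer seed; output is deterministic given it.
#' @return A new [audio_recording()] with provenance `"noise_augmented"`
#'   and `parent_id` attribute set to the input id.
#' @export
add_white_noise <- function(rec, snr_db = 20, seed = 1L) {
  stopifnot(inherits(rec, "audio_recording"), is.finite(snr_db))
  p_sig <- mean(rec$samples^2)
  if (p_sig == 0) {
    stop("silent input: SNR is undefined for zero-power audio", call. = FALSE)
  }
  sd_noise <- sqrt(p_sig / 10^(snr_db / 10))
  noise <- with_seed(seed, stats::rnorm(length(rec$samples), sd = sd_noise))
  out <- audio_recording(rec$samples + noise, rec$rate, label = rec$label,
                         id = paste0(rec$id, "_noise"),
                         provenance = "noise_augmented")
  attr(out, "parent_id") <- rec$id
  out
}

#' Clip a short and a long segment from a recording
#'
#' Extracts two contiguous sub-intervals with seeded random starts: one of
#' duration drawn uniformly in \[3, 6\] s and one in \[18, 21\] s, the
#' clipping scheme used to expand 24-30 s recordings into more training
#' samples. Labels are inherited.
#'
#' @param rec An [audio_recording()] of duration at least 21 s.
#' @param seed Integer seed.
#' @return A list of two [audio_recording()]s with provenances
#'   `"clip_3_6"` and `"clip_18_21"`.
#' @export
clip_segments <- function(rec, seed = 1L) {
  stopifnot(inherits(rec, "audio_recording"))
  dur <- duration(rec)
  if (dur < 21) {
    stop("recording too short to clip: need >= 21 s, have ",
         sprintf("%.2f", dur), " s", call. = FALSE)
  }
  with_seed(seed, {
    d_short <- stats::runif(1, 3, 6)
    d_long <- stats::runif(1, 18, min(21, dur))
    s_short <- stats::runif(1, 0, dur - d_short)
    s_long <- stats::runif(1, 0, dur - d_long)
    mk <- function(start, d, prov, suffix) {
      i0 <- 1L + round(start * rec$rate)
      i1 <- i0 + round(d * rec$rate) - 1L
      out <- audio_recording(rec$samples[i0:i1], rec$rate, label = rec$label,
                             id = paste0(rec$id, suffix), provenance = prov)
      attr(out, "parent_id") <- rec$id
      out
    }
    list(mk(s_short, d_short, "clip_3_6", "_c36"),
         mk(s_long, d_long, "clip_18_21", "_c1821"))
  })
}

#' Expand and class-balance a dataset by clipping and noise injection
#'
#' Every normal original yields its two clips (2 variants); every abnormal
#' original yields its two clips, the noise-augmented full-length variant
#' with its two clips, and the full-length clean recording itself
#' (6 variants). With the clinical composition of 600 normal and 200
#' abnormal originals this returns 2,400 recordings, 1,200 per class.
#'
#' @param originals A manifest tibble from [generate_dataset()] (columns
#'   `id`, `label`, list-column `rec`) or a list of [audio_recording()]s.
#' @param snr_db SNR for the noise-augmented variants (dB), default 20.
#' @param seed Integer seed.
#' @return An expanded manifest tibble with columns `id`, `label`,
#'   `provenance`, `parent_id`, `duration`, `rate` and list-column `rec`.
#' @export
expand_and_balance <- function(originals, snr_db = 20, seed = 1L) {
  recs <- manifest_recs(originals)
  if (length(recs) == 0L) stop("empty input dataset", call. = FALSE)
  labels <- vapply(recs, function(r) r$label, character(1))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to balance the dataset", call. = FALSE)
  }
  seeds <- derive_seeds(seed, 3L * length(recs))
  out <- list()
  k <- 0L
  add <- function(r, parent) {
    k <<- k + 1L
    if (is.null(attr(r, "parent_id"))) attr(r, "parent_id") <- parent
    out[[k]] <<- r
  }
  for (i in seq_along(recs)) {
    r <- recs[[i]]
    clips <- clip_segments(r, seed = seeds[3L * i - 2L])
    add(clips[[1]], r$id); add(clips[[2]], r$id)
    if (r$label == "abnormal") {
      noisy <- add_white_noise(r, snr_db = snr_db, seed = seeds[3L * i - 1L])
      nclips <- clip_segments(noisy, seed = seeds[3L * i])
      add(nclips[[1]], r$id); add(nclips[[2]], r$id)
      add(noisy, r$id)
      add(r, r$id)
    }
  }
  recs_to_manifest(out)
}

#' Stratified train/validation/test split
#'
#' Randomly partitions an expanded dataset into train, validation and test
#' subsets, stratified by label. Global subset sizes are
#' `floor(N * ratio)` for validation and test with the remainder assigned
#' to train; sizes are apportioned across classes by largest remainder so
#' each subset's class counts differ by at most one from exact
#' proportionality.
#'
#' @param expanded Manifest tibble (or list of recordings) to split.
#' @param ratios Length-3 numeric `(train, validation, test)` summing
#'   to 1; default `c(0.7, 0.1, 0.2)`.
#' @param seed Integer seed; membership is deterministic given it.
#' @return A `dataset_split` list with manifest tibbles `train`,
#'   `validation`, `test` and the `seed`.
#' @export
split_dataset <- function(expanded, ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3, abs(sum(ratios) - 1) < 1e-8)
  man <- if (tibble::is_tibble(expanded)) expanded else recs_to_manifest(expanded)
  n <- nrow(man)
  if (n == 0L) stop("cannot split an empty dataset", call. = FALSE)
  n_val <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])

  classes <- sort(unique(man$label))
  class_n <- vapply(classes, function(cl) sum(man$label == cl), integer(1))
  alloc_val <- largest_remainder(n_val * class_n / n)
  alloc_test <- largest_remainder(n_test * class_n / n)

  assign_split <- rep("train", n)
  for (ci in seq_along(classes)) {
    idx <- which(man$label == classes[ci])
    idx <- with_seed(seed + ci, sample(idx))
    nv <- alloc_val[ci]; nt <- alloc_test[ci]
    if (nv > 0) assign_split[idx[seq_len(nv)]] <- "validation"
    if (nt > 0) assign_split[idx[nv + seq_len(nt)]] <- "test"
  }
  man$split <- assign_split
  structure(list(train = man[man$split == "train", ],
                 validation = man[man$split == "validation", ],
                 test = man[man$split == "test", ],
                 seed = as.integer(seed)),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split> train %d / validation %d / test %d (seed %d)\n",
              nrow(x$train), nrow(x$validation), nrow(x$test), x$seed))
  invisible(x)
}

# Integer apportionment with quotas summing to sum(round down + remainders).
largest_remainder <- function(quota) {
  base <- floor(quota)
  rem <- sum(round(sum(quota))) - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

manifest_recs <- function(x) {
  if (tibble::is_tibble(x)) x$rec else x
}

recs_to_manifest <- function(recs) {
  tibble::tibble(
    id = vapply(recs, function(r) r$id, character(1)),
    label = vapply(recs, function(r) r$label, character(1)),
    provenance = vapply(recs, function(r) r$provenance, character(1)),
    parent_id = vapply(recs, function(r) {
      p <- attr(r, "parent_id"); if (is.null(p)) NA_character_ else p
    }, character(1)),
    duration = vapply(recs, duration, numeric(1)),
    rate = vapply(recs, function(r) r$rate, numeric(1)),
    rec = recs
  )
}
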