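#' Confusion matrix and derived classification metrics
#'
#' Counts TP/FP/TN/FN (positive class = abnormal = 1) and computes
#' precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 (harmonic mean of the
#' two) and accuracy `(TP+TN)/N`. Degenerate ratios (zero denominator) are
#' reported as `NA` rather than 0 so aggregates are never silently
#' optimistic.
#'
#' @param labels True labels: 0/1 numeric or `"normal"`/`"abnormal"`.
#' @param predictions Predicted labels, same coding.
#' @param scores Optional probabilities for the positive class; when given
#'   (with both classes present) AUROC is included.
#' @param threshold Threshold recorded in the report (bookkeeping only).
#' @return An `eval_report` list with counts and metrics.
#' @export
confusion_and_metrics <- function(labels, predictions, scores = NULL,
                                  threshold = 0.5) {
  y <- coerce01(labels)
  p <- coerce01(predictions)
  if (length(y) != length(p)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  if (length(y) < 1L) stop("need at least one sample", call. = FALSE)
  tp <- sum(y == 1 & p == 1)
  fp <- sum(y == 0 & p == 1)
  tn <- sum(y == 0 & p == 0)
  fn <- sum(y == 1 & p == 0)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  auroc <- if (!is.null(scores) && length(unique(y)) == 2L) {
    roc_auc(y, scores)$auroc
  } else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 precision = precision, recall = recall, f1 = f1,
                 accuracy = (tp + tn) / length(y), auroc = auroc,
                 threshold = threshold, n = length(y)),
            class = "eval_report")
}

coerce01 <- function(x) {
  if (is.character(x) || is.factor(x)) as.numeric(as.character(x) == "abnormal")
  else as.numeric(x)
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> n=%d  TP=%d FP=%d TN=%d FN=%d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f  AUROC %s\n",
              x$precision, x$recall, x$f1, x$accuracy,
              ifelse(is.na(x$auroc), "NA", sprintf("%.4f", x$auroc))))
  invisible(x)
}

#' @rdname confusion_and_metrics
#' @param x,... An `eval_report`; further arguments ignored.
#' @method tidy eval_report
#' @export
tidy.eval_report <- function(x, ...) {
  tibble::tibble(metric = c("precision", "recall", "f1", "accuracy", "auroc"),
                 value = c(x$precision, x$recall, x$f1, x$accuracy, x$auroc))
}

#' @rdname confusion_and_metrics
#' @method glance eval_report
#' @export
glance.eval_report <- function(x, ...) {
  tibble::tibble(n = x$n, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
                 precision = x$precision, recall = x$recall, f1 = x$f1,
                 accuracy = x$accuracy, auroc = x$auroc,
                 threshold = x$threshold)
}

#' ROC curve and AUROC
#'
#' AUROC via the Mann-Whitney rank statistic (ties averaged): the
#' probability that a random positive scores above a random negative. The
#' curve lists (FPR, TPR) at every distinct score threshold.
#'
#' @param labels 0/1 numeric or `"normal"`/`"abnormal"`; both classes must
#'   be present.
#' @param scores Numeric scores, larger = more abnormal.
#' @return List with `auroc` and a `curve` tibble (`threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(labels, scores) {
  y <- coerce01(labels)
  if (length(y) != length(scores)) {
    stop("labels and scores differ in length", call. = FALSE)
  }
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute a ROC curve", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  auroc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n_neg, numeric(1))
  structure(list(auroc = auroc,
                 curve = tibble::tibble(threshold = thr, fpr = fpr, tpr = tpr)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUROC %.4f (%d thresholds)\n", x$auroc,
              nrow(x$curve)))
  invisible(x)
}

#' Plot a ROC curve
#'
#' @param object A `roc_result` from [roc_auc()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot roc_result
#' @export
autoplot.roc_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUROC = %.3f", object$auroc)) +
    ggplot2::theme_minimal()
}

#' Peak signal-to-noise ratio between two images
#'
#' `10 * log10(MAX^2 / MSE)`; identical images (zero MSE) return `Inf`.
#'
#' @param a,b Equal-shaped numeric matrices or arrays.
#' @param max_value Maximum possible pixel value (1 for normalized feature
#'   images).
#' @return PSNR in dB.
#' @export
psnr <- function(a, b, max_value = 1) {
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical shapes", call. = FALSE)
  }
  mse <- mean((a - b)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Structural similarity index (global statistics)
#'
#' Single-window SSIM
#' `((2*mu_x*mu_y + C1) * (2*sigma_xy + C2)) /
#'  ((mu_x^2 + mu_y^2 + C1) * (sigma_x^2 + sigma_y^2 + C2))`
#' with means, variances and covariance over the whole image and
#' stabilizers `C1 = (0.01*MAX)^2`, `C2 = (0.03*MAX)^2`.
#'
#' @param a,b Equal-shaped numeric matrices or arrays.
#' @param max_value Maximum possible pixel value.
#' @return SSIM in \[-1, 1\]; 1 for identical images.
#' @export
ssim <- function(a, b, max_value = 1) {
  if (!identical(dim(a), dim(b))) {
    stop("images must have identical shapes", call. = FALSE)
  }
  c1 <- (0.01 * max_value)^2
  c2 <- (0.03 * max_value)^2
  mu_x <- mean(a); mu_y <- mean(b)
  var_x <- mean((a - mu_x)^2); var_y <- mean((b - mu_y)^2)
  cov_xy <- mean((a - mu_x) * (b - mu_y))
  ((2 * mu_x * mu_y + c1) * (2 * cov_xy + c2)) /
    ((mu_x^2 + mu_y^2 + c1) * (var_x + var_y + c2))
}

#' Between-class spectrogram difference per feature type
#'
#' Draws `n_samples` seeded normal/abnormal recording pairs, featurizes
#' each member, and reports mean PSNR and SSIM between the paired
#' normalized images for the Mel spectrogram, the MFCC matrix and the
#' fused feature. Lower PSNR/SSIM means a larger between-class difference,
#' i.e. a more discriminative representation.
#'
#' @param normal_recs,abnormal_recs Lists of [audio_recording()]s (or
#'   manifest tibbles with a `rec` column).
#' @param n_samples Number of pairs to draw (default 50).
#' @param seed Integer seed for the pairing.
#' @param mu Pre-emphasis coefficient.
#' @return A `spectral_diff` tibble with columns `feature`, `psnr_db`,
#'   `ssim`, `n_pairs`.
#' @export
compare_feature_types <- function(normal_recs, abnormal_recs,
                                  n_samples = 50L, seed = 1L, mu = 0.97) {
  normal_recs <- manifest_recs(normal_recs)
  abnormal_recs <- manifest_recs(abnormal_recs)
  if (length(normal_recs) == 0L || length(abnormal_recs) == 0L) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  if (n_samples > length(normal_recs) * length(abnormal_recs)) {
    stop("n_samples exceeds the number of available pairs", call. = FALSE)
  }
  pairs <- with_seed(seed, cbind(
    sample(length(normal_recs), n_samples, replace = n_samples > length(normal_recs)),
    sample(length(abnormal_recs), n_samples, replace = n_samples > length(abnormal_recs))
  ))
  feats <- function(rec) {
    y <- pre_emphasize(rec, mu = mu)
    lm <- log_mel_native(y)
    mel <- normalize_columns(resize_time_axis(lm, 128L))
    mfcc <- normalize_columns(
      resize_time_axis(dct_matrix(13L, nrow(lm)) %*% lm, 128L))
    list(mel = mel, mfcc = mfcc,
         fused = normalize_columns(fuse_features(mel, mfcc)))
  }
  acc <- matrix(0, 3, 2, dimnames = list(c("mel", "mfcc", "fused"),
                                         c("psnr", "ssim")))
  for (k in seq_len(n_samples)) {
    fa <- feats(normal_recs[[pairs[k, 1]]])
    fb <- feats(abnormal_recs[[pairs[k, 2]]])
    for (ft in rownames(acc)) {
      acc[ft, "psnr"] <- acc[ft, "psnr"] + psnr(fa[[ft]], fb[[ft]])
      acc[ft, "ssim"] <- acc[ft, "ssim"] + ssim(fa[[ft]], fb[[ft]])
    }
  }
  out <- tibble::tibble(
    feature = c("Mel spectrogram", "MFCC", "Fused feature"),
    psnr_db = acc[, "psnr"] / n_samples,
    ssim = acc[, "ssim"] / n_samples,
    n_pairs = as.integer(n_samples)
  )
  class(out) <- c("spectral_diff", class(out))
  out
}
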