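test_that("confusion metrics reproduce the worked clinical-test example", {
  # TP=233, FP=2, TN=238, FN=7 (480 test samples)
  y <- c(rep(1, 233), rep(0, 2), rep(0, 238), rep(1, 7))
  p <- c(rep(1, 233), rep(1, 2), rep(0, 238), rep(0, 7))
  rep_ <- confusion_and_metrics(y, p)
  expect_equal(rep_$tp, 233); expect_equal(rep_$fp, 2)
  expect_equal(rep_$tn, 238); expect_equal(rep_$fn, 7)
  expect_equal(round(rep_$precision, 2), 0.99)
  expect_equal(round(rep_$recall, 2), 0.97)
  expect_equal(round(rep_$f1, 2), 0.98)
  expect_equal(rep_$precision, 233 / 235, tolerance = 1e-12)
  expect_equal(rep_$recall, 233 / 240, tolerance = 1e-12)
  expect_equal(rep_$accuracy, 471 / 480, tolerance = 1e-12)
  td <- tidy(rep_)
  expect_equal(td$value[td$metric == "f1"], rep_$f1)
})

test_that("perfect and degenerate predictions are handled", {
  y <- c(1, 0, 1, 0)
  rep_ <- confusion_and_metrics(y, y)
  expect_equal(rep_$precision, 1); expect_equal(rep_$recall, 1)
  expect_equal(rep_$f1, 1); expect_equal(rep_$accuracy, 1)
  # no predicted positives -> precision undefined (NA), not zero
  rep0 <- confusion_and_metrics(y, c(0, 0, 0, 0))
  expect_true(is.na(rep0$precision))
  expect_equal(rep0$recall, 0)
  expect_error(confusion_and_metrics(c(1, 0), c(1)), "length")
})

test_that("confusion counts match a brute-force loop oracle", {
  set.seed(30)
  for (r in 1:3) {
    y <- stats::rbinom(20, 1, 0.4)
    p <- stats::rbinom(20, 1, 0.5)
    rep_ <- confusion_and_metrics(y, p)
    tp <- fp <- tn <- fn <- 0
    for (i in 1:20) {
      if (y[i] == 1 && p[i] == 1) tp <- tp + 1
      if (y[i] == 0 && p[i] == 1) fp <- fp + 1
      if (y[i] == 0 && p[i] == 0) tn <- tn + 1
      if (y[i] == 1 && p[i] == 0) fn <- fn + 1
    }
    expect_equal(c(rep_$tp, rep_$fp, rep_$tn, rep_$fn), c(tp, fp, tn, fn))
    expect_equal(rep_$accuracy, (tp + tn) / 20)
  }
})

test_that("AUROC: separation, null behaviour, and the pair-counting oracle", {
  y <- rep(c(0, 1), each = 10)
  expect_equal(roc_auc(y, c(stats::runif(10, 0, 0.4), stats::runif(10, 0.6, 1)))$auroc, 1)
  set.seed(31)
  y_big <- stats::rbinom(1000, 1, 0.5)
  s_big <- stats::runif(1000)
  expect_equal(roc_auc(y_big, s_big)$auroc, 0.5, tolerance = 0.1)
  # O(N^2) concordant-pair oracle with tie halving
  set.seed(32)
  y10 <- c(0, 0, 0, 0, 1, 1, 1, 0, 1, 1)
  s10 <- round(stats::runif(10), 1)                # induce ties
  pos <- which(y10 == 1); neg <- which(y10 == 0)
  conc <- 0
  for (i in pos) for (j in neg) {
    conc <- conc + (s10[i] > s10[j]) + 0.5 * (s10[i] == s10[j])
  }
  expect_equal(roc_auc(y10, s10)$auroc, conc / (length(pos) * length(neg)))
  expect_error(roc_auc(rep(1, 5), stats::runif(5)), "both classes")
})

test_that("AUROC is invariant under monotone score transforms and matches pROC", {
  set.seed(33)
  y <- stats::rbinom(60, 1, 0.5)
  s <- stats::rnorm(60) + y
  a1 <- roc_auc(y, s)$auroc
  expect_equal(roc_auc(y, exp(s))$auroc, a1)
  expect_equal(roc_auc(y, 3 * s - 7)$auroc, a1)
  # independent cross-check against pROC
  a_ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
  expect_equal(a1, a_ref, tolerance = 1e-12)
})

test_that("the ROC curve starts at (0,0) and ends at (1,1)", {
  set.seed(34)
  r <- roc_auc(stats::rbinom(40, 1, 0.5), stats::runif(40))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_equal(r$curve$tpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
})

test_that("PSNR matches its closed forms and ordering", {
  a <- matrix(0.5, 8, 8)
  expect_equal(psnr(a, a + 0.1), 20)               # MSE 0.01, MAX 1
  expect_equal(psnr(a, a + 1), 0)                  # MSE 1
  expect_identical(psnr(a, a), Inf)
  b1 <- a + 0.05; b2 <- a + 0.2
  expect_gt(psnr(a, b1), psnr(a, b2))              # PSNR falls as MSE grows
  expect_error(psnr(a, matrix(0, 4, 4)), "shape")
})

test_that("SSIM: identity, symmetry, and the direct-formula oracle", {
  set.seed(35)
  x <- matrix(stats::runif(64), 8, 8)
  y <- matrix(stats::runif(64), 8, 8)
  expect_equal(ssim(x, x), 1)
  expect_equal(ssim(matrix(0.3, 4, 4), matrix(0.3, 4, 4)), 1)
  expect_equal(ssim(x, y), ssim(y, x))
  c1 <- 0.01^2; c2 <- 0.03^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  oracle <- ((2 * mx * my + c1) * (2 * cxy + c2)) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
  expect_equal(ssim(x, y), oracle, tolerance = 1e-10)
  expect_gte(ssim(x, y), -1); expect_lte(ssim(x, y), 1)
})

test_that("feature comparison reports one row per representation", {
  dat <- fixture_clips()
  norm <- dat$clips[dat$labels == "normal"][1:8]
  abn <- dat$clips[dat$labels == "abnormal"][1:8]
  tab <- compare_feature_types(norm, abn, n_samples = 6, seed = 2)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$feature, c("Mel spectrogram", "MFCC", "Fused feature"))
  expect_true(all(tab$n_pairs == 6))
  expect_true(all(tab$ssim >= -1 & tab$ssim <= 1))
  expect_error(compare_feature_types(norm, list(), 5), "non-empty")
  expect_error(compare_feature_types(norm[1:2], abn[1:2], n_samples = 100),
               "exceeds")
})

test_that("identical members compare at the SSIM/PSNR ceiling", {
  dat <- fixture_clips()
  same <- dat$clips[dat$labels == "normal"][c(1, 1)]
  tab <- compare_feature_types(same, same, n_samples = 2, seed = 3)
  expect_true(all(tab$ssim == 1))
  expect_true(all(is.infinite(tab$psnr_db)))
})

test_that("between-class SSIM is below within-class SSIM for fused features", {
  dat <- fixture_clips()
  norm <- dat$clips[dat$labels == "normal"]
  abn <- dat$clips[dat$labels == "abnormal"]
  worse <- 0
  for (rep_i in 1:3) {
    between <- compare_feature_types(norm[1:10], abn[1:10], n_samples = 6,
                                     seed = 40 + rep_i)
    within <- compare_feature_types(norm[1:10], norm[11:20], n_samples = 6,
                                    seed = 40 + rep_i)
    if (between$ssim[3] < within$ssim[3]) worse <- worse + 1
  }
  expect_gte(worse, 2)
})
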