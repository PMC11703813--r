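test_that("channel attention has the right shape, range, and arithmetic", {
  set.seed(10)
  fmap <- array(stats::rnorm(2 * 2 * 2), c(2, 2, 2))
  params <- cbam_params(channels = 2, reduction = 2, kernel = 3, seed = 5)
  w <- channel_attention(fmap, params = params)
  expect_equal(dim(w), c(2L, 1L, 1L))
  expect_true(all(w > 0 & w < 1))
  # independent hand-computed forward pass
  m <- matrix(fmap, 2, 4)
  s_avg <- c(mean(m[1, ]), mean(m[2, ]))
  s_max <- c(max(m[1, ]), max(m[2, ]))
  mlp <- function(s) params$A2 %*% pmax(params$A1 %*% s, 0)
  expected <- 1 / (1 + exp(-(mlp(s_avg) + mlp(s_max))))
  expect_equal(as.vector(w), as.vector(expected), tolerance = 1e-6)
  expect_error(cbam_params(2, reduction = 5), "reduction")
})

test_that("spatial attention: shape, range, and the zero-weight fixed point", {
  set.seed(11)
  fmap <- array(stats::rnorm(3 * 4 * 5), c(3, 4, 5))
  w <- spatial_attention(fmap, kernel = 3, seed = 2)
  expect_equal(dim(w), c(1L, 4L, 5L))
  expect_true(all(w > 0 & w < 1))
  # zero convolution weights (bias-free) give sigmoid(0) = 0.5 everywhere
  params0 <- cbam_params(3, reduction = 1, kernel = 3, seed = 1)
  params0$Wsp[] <- 0
  w0 <- spatial_attention(array(1, c(3, 4, 5)), params = params0)
  expect_true(all(w0 == 0.5))
  expect_error(spatial_attention(fmap, kernel = 4), "odd")
})

test_that("apply_cbam broadcasts, preserves shape, and contracts", {
  set.seed(12)
  fmap <- array(stats::runif(3 * 4 * 5), c(3, 4, 5))
  ones <- list(channel_weights = array(1, c(3, 1, 1)),
               spatial_weights = array(1, c(1, 4, 5)))
  expect_equal(apply_cbam(fmap, ones), fmap)
  cw <- array(stats::runif(3, 0.1, 0.9), c(3, 1, 1))
  sw <- array(stats::runif(20, 0.1, 0.9), c(1, 4, 5))
  out <- apply_cbam(fmap, list(channel_weights = cw, spatial_weights = sw))
  expect_equal(dim(out), dim(fmap))
  expect_true(all(abs(out) <= abs(fmap)))
  # triple-loop oracle
  oracle <- fmap
  for (c in 1:3) for (h in 1:4) for (w in 1:5) {
    oracle[c, h, w] <- fmap[c, h, w] * cw[c, 1, 1] * sw[1, h, w]
  }
  expect_equal(out, oracle)
  expect_error(apply_cbam(fmap, list(channel_weights = array(1, c(2, 1, 1)))),
               "channel_weights")
})

test_that("the batched CBAM layer agrees with the standalone operators", {
  set.seed(13)
  C <- 4L; H <- 6L; W <- 5L
  fmap <- array(stats::rnorm(C * H * W), c(C, H, W))
  layer <- bruitnet:::layer_cbam(C, reduction = 2L, kernel = 3L, seed = 9)
  params <- list(A1 = layer$P$A1, A2 = layer$P$A2, Wsp = layer$P$Wsp)
  # channels-first -> engine layout (H, W, N = 1, C)
  x <- array(aperm(fmap, c(2, 3, 1)), c(H, W, 1L, C))
  y_layer <- layer$fwd(x, train = FALSE)
  ref <- cbam_forward(fmap, params = params)
  y_ref <- array(aperm(ref$output, c(2, 3, 1)), c(H, W, 1L, C))
  expect_equal(y_layer, y_ref, tolerance = 1e-12)
})

test_that("CBAM gradients agree with finite differences", {
  set.seed(14)
  C <- 3L; H <- 5L; W <- 4L; N <- 2L
  layer <- bruitnet:::layer_cbam(C, reduction = 3L, kernel = 3L, seed = 4)
  x <- array(stats::rnorm(H * W * N * C), c(H, W, N, C))
  proj <- array(stats::rnorm(H * W * N * C), c(H, W, N, C))
  loss <- function(xx) sum(layer$fwd(xx, train = FALSE) * proj)
  base <- layer$fwd(x, train = TRUE)
  dx <- layer$bwd(proj)
  eps <- 1e-6
  idx <- sample(length(x), 12)
  for (i in idx) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    num <- (loss(xp) - loss(xm)) / (2 * eps)
    expect_equal(dx[i], num, tolerance = 1e-4)
  }
  # parameter gradients
  layer$fwd(x, train = TRUE); layer$bwd(proj)
  for (nm in names(layer$P)) {
    g <- layer$G[[nm]]
    for (i in sample(length(layer$P[[nm]]), min(4, length(layer$P[[nm]])))) {
      old <- layer$P[[nm]][i]
      layer$P[[nm]][i] <- old + eps; lp <- loss(x)
      layer$P[[nm]][i] <- old - eps; lm <- loss(x)
      layer$P[[nm]][i] <- old
      expect_equal(g[i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})
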