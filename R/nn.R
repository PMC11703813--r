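# Minimal reverse-mode neural-network engine used by the CBAM-LSTM
# classifier. Activations between convolutional layers are 4-d arrays of
# dim (H, W, N, C) — height, width, batch, channels. Putting channels last
# makes every per-channel reduction a colMeans/colSums over a (H*W*N, C)
# matrix view and every per-channel broadcast a rep(..., each = H*W*N),
# so no aperm() is needed anywhere in the convolutional stack (R arrays
# are column-major; aperm copies dominate runtime otherwise). The
# recurrent head works on (N, D) matrices. Each layer is an environment
# with closures fwd(x, train) / bwd(dy), parameter list P and gradient
# list G; gradients are hand-derived and verified by finite-difference
# tests.

# Broadcast a length-C vector over the leading dims of an (..., C) array.
bcast <- function(v, n_lead) rep(v, each = n_lead)

# 'same' convolution, stride 1: x (H,W,N,Cin), W_arr (kh,kw,Cin,Cout).
# Returns list(y = (H,W,N,Cout), cols = im2col matrix (H*W*N, kh*kw*Cin)).
conv2d_forward <- function(x, W_arr, b = NULL, pad = (dim(W_arr)[1] - 1) %/% 2) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  kh <- dim(W_arr)[1]; kw <- dim(W_arr)[2]; Cout <- dim(W_arr)[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, N, C))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  cols <- matrix(0, H * W * N, kh * kw * C)
  k <- 0L
  for (c in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    cols[, k] <- xp[di:(di + H - 1L), dj:(dj + W - 1L), , c]
  }
  y <- cols %*% matrix(W_arr, kh * kw * C, Cout)
  if (!is.null(b)) y <- y + bcast(b, H * W * N)
  dim(y) <- c(H, W, N, Cout)
  list(y = y, cols = cols)
}

# Swap in/out channels and rotate the kernel 180 degrees (for input
# gradients of a 'same' convolution).
conv2d_flip <- function(W_arr) {
  kh <- dim(W_arr)[1]; kw <- dim(W_arr)[2]
  aperm(W_arr[kh:1, kw:1, , , drop = FALSE], c(1, 2, 4, 3))
}

# Shift-and-accumulate 'same' convolution for few-channel maps (the CBAM
# spatial path): same arithmetic as conv2d_forward without the im2col
# matrix, which would be kernel^2 times larger than the 1-2 channel input.
conv2d_small <- function(x, W_arr, pad = (dim(W_arr)[1] - 1) %/% 2) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  kh <- dim(W_arr)[1]; kw <- dim(W_arr)[2]; Cout <- dim(W_arr)[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, N, C))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  y <- array(0, c(H, W, N, Cout))
  for (co in seq_len(Cout)) {
    acc <- numeric(H * W * N)
    for (c in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
      w <- W_arr[di, dj, c, co]
      if (w == 0) next
      acc <- acc + w * xp[di:(di + H - 1L), dj:(dj + W - 1L), , c]
    }
    y[, , , co] <- acc
  }
  y
}

# Gradient of conv2d_small w.r.t. its kernel: per-offset inner products.
conv2d_small_gradw <- function(x, dy, kdim, pad = (kdim[1] - 1) %/% 2) {
  d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]; C <- d[4]
  kh <- kdim[1]; kw <- kdim[2]; Cout <- kdim[4]
  xp <- array(0, c(H + 2 * pad, W + 2 * pad, N, C))
  xp[pad + seq_len(H), pad + seq_len(W), , ] <- x
  g <- array(0, kdim)
  for (co in seq_len(Cout)) {
    dyc <- as.vector(dy[, , , co])
    for (c in seq_len(C)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
      g[di, dj, c, co] <-
        sum(xp[di:(di + H - 1L), dj:(dj + W - 1L), , c] * dyc)
    }
  }
  g
}

he_init <- function(dims, fan_in, seed) {
  with_seed(seed, array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims))
}

glorot_init <- function(nr, nc, seed) {
  lim <- sqrt(6 / (nr + nc))
  with_seed(seed, matrix(stats::runif(nr * nc, -lim, lim), nr, nc))
}

layer_conv2d <- function(in_c, out_c, k = 3L, seed = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "conv2d"
  e$P <- list(W = he_init(c(k, k, in_c, out_c), k * k * in_c, seed),
              b = numeric(out_c))
  e$G <- list()
  e$fwd <- function(x, train = TRUE) {
    cf <- conv2d_forward(x, e$P$W, e$P$b)
    e$cache <- list(cols = cf$cols, d = dim(x))
    cf$y
  }
  e$bwd <- function(dy) {
    d <- dim(dy)
    dym <- matrix(dy, prod(d[1:3]), d[4])
    e$G$W <- array(crossprod(e$cache$cols, dym), dim(e$P$W))
    e$G$b <- colSums(dym)
    wf <- conv2d_flip(e$P$W)
    # input gradient: shift-accumulate when few output channels, so the
    # kernel^2 * C_out-wide im2col temporary is never materialized
    dx <- if (in_c <= 4L) conv2d_small(dy, wf) else conv2d_forward(dy, wf)$y
    e$cache <- NULL
    dx
  }
  e
}

layer_leaky_relu <- function(slope = 0.01) {
  e <- new.env(parent = emptyenv())
  e$type <- "leaky_relu"; e$P <- list(); e$G <- list()
  e$fwd <- function(x, train = TRUE) {
    pos <- x >= 0
    e$cache <- pos
    x * (slope + (1 - slope) * pos)
  }
  e$bwd <- function(dy) {
    dx <- dy * (slope + (1 - slope) * e$cache)
    e$cache <- NULL
    dx
  }
  e
}

layer_batchnorm <- function(C, momentum = 0.9, eps = 1e-5) {
  e <- new.env(parent = emptyenv())
  e$type <- "batchnorm"
  e$P <- list(gamma = rep(1, C), beta = rep(0, C))
  e$G <- list()
  e$run_mean <- rep(0, C); e$run_var <- rep(1, C); e$seen <- FALSE
  e$collecting <- FALSE
  e$fwd <- function(x, train = TRUE) {
    d <- dim(x)
    n <- prod(d[-length(d)])
    m <- matrix(x, n, C)
    if (train || e$collecting) {
      mu <- colMeans(m)
      v <- colMeans(m^2) - mu^2
      if (e$collecting) {
        e$acc_mean <- e$acc_mean + mu
        e$acc_var <- e$acc_var + v
        e$acc_n <- e$acc_n + 1L
      } else {
        e$run_mean <- if (e$seen) momentum * e$run_mean + (1 - momentum) * mu else mu
        e$run_var <- if (e$seen) momentum * e$run_var + (1 - momentum) * v else v
        e$seen <- TRUE
      }
    } else {
      mu <- e$run_mean; v <- e$run_var
    }
    invstd <- 1 / sqrt(v + eps)
    xhat <- (m - bcast(mu, n)) * bcast(invstd, n)
    if (train && !e$collecting) {
      e$cache <- list(xhat = xhat, invstd = invstd, d = d)
    }
    y <- xhat * bcast(e$P$gamma, n) + bcast(e$P$beta, n)
    dim(y) <- d
    y
  }
  e$bwd <- function(dy) {
    cc <- e$cache
    n <- prod(cc$d[-length(cc$d)])
    dm <- matrix(dy, n, C)
    e$G$gamma <- colSums(dm * cc$xhat)
    e$G$beta <- colSums(dm)
    dxhat <- dm * bcast(e$P$gamma, n)
    dxm <- (dxhat - bcast(colSums(dxhat) / n, n) -
              cc$xhat * bcast(colSums(dxhat * cc$xhat) / n, n)) *
      bcast(cc$invstd, n)
    dim(dxm) <- cc$d
    e$cache <- NULL
    dxm
  }
  e
}

layer_maxpool2 <- function() {
  e <- new.env(parent = emptyenv())
  e$type <- "maxpool2"; e$P <- list(); e$G <- list()
  e$fwd <- function(x, train = TRUE) {
    d <- dim(x); H2 <- d[1] %/% 2L; W2 <- d[2] %/% 2L
    ri <- seq(1L, 2L * H2, 2L); ci <- seq(1L, 2L * W2, 2L)
    offs <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
    best <- x[ri, ci, , , drop = FALSE]
    bestk <- array(1L, dim(best))
    for (k in 2:4) {
      cand <- x[ri + offs[[k]][1], ci + offs[[k]][2], , , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      bestk[upd] <- k
    }
    e$cache <- list(bestk = bestk, d = d, ri = ri, ci = ci, offs = offs)
    best
  }
  e$bwd <- function(dy) {
    cc <- e$cache
    dx <- array(0, cc$d)
    for (k in 1:4) {
      mask <- cc$bestk == k
      if (!any(mask)) next
      sl <- dx[cc$ri + cc$offs[[k]][1], cc$ci + cc$offs[[k]][2], , , drop = FALSE]
      sl[mask] <- dy[mask]
      dx[cc$ri + cc$offs[[k]][1], cc$ci + cc$offs[[k]][2], , ] <- sl
    }
    e$cache <- NULL
    dx
  }
  e
}

layer_dropout <- function(p = 0.3) {
  e <- new.env(parent = emptyenv())
  e$type <- "dropout"; e$P <- list(); e$G <- list()
  e$fwd <- function(x, train = TRUE) {
    if (!train || p <= 0) {
      e$cache <- NULL
      return(x)
    }
    mask <- (stats::runif(length(x)) >= p) / (1 - p)
    dim(mask) <- dim(x)
    e$cache <- mask
    x * mask
  }
  e$bwd <- function(dy) {
    if (is.null(e$cache)) return(dy)
    dx <- dy * e$cache
    e$cache <- NULL
    dx
  }
  e
}

# Convolutional block attention: channel attention (dual-pooled shared
# bottleneck MLP, sigmoid) followed by spatial attention (channel mean/max
# maps, k x k conv, sigmoid), each applied multiplicatively.
layer_cbam <- function(C, reduction = 16L, kernel = 7L, seed = 1L) {
  if (reduction < 1L || reduction > C) {
    stop("cbam reduction must satisfy 1 <= reduction <= channels", call. = FALSE)
  }
  if (kernel %% 2L == 0L) stop("cbam spatial kernel must be odd", call. = FALSE)
  Cr <- max(1L, C %/% reduction)
  e <- new.env(parent = emptyenv())
  e$type <- "cbam"
  e$P <- list(A1 = glorot_init(Cr, C, seed),
              A2 = glorot_init(C, Cr, seed + 1L),
              Wsp = he_init(c(kernel, kernel, 2L, 1L), kernel * kernel * 2,
                            seed + 2L))
  e$G <- list()
  e$fwd <- function(x, train = TRUE) {
    d <- dim(x); H <- d[1]; W <- d[2]; N <- d[3]
    HW <- H * W; HWN <- HW * N
    mx <- matrix(x, HW, N * C)                      # cols ordered (n, c)
    s_avg <- matrix(colMeans(mx), N, C)
    amax <- max.col(t(mx), ties.method = "first")
    s_max <- matrix(mx[cbind(amax, seq_len(N * C))], N, C)
    h_a <- pmax(s_avg %*% t(e$P$A1), 0)             # (N, Cr)
    h_m <- pmax(s_max %*% t(e$P$A1), 0)
    a <- sigmoid((h_a + h_m) %*% t(e$P$A2))         # (N, C)
    f1 <- x * bcast(as.vector(a), HW)

    mt <- matrix(f1, HWN, C)
    sp_mean <- rowMeans(mt)
    cmax <- max.col(mt, ties.method = "first")
    sp_max <- mt[cbind(seq_len(HWN), cmax)]
    spin <- array(c(sp_mean, sp_max), c(H, W, N, 2L))
    s <- sigmoid(conv2d_small(spin, e$P$Wsp))       # (H, W, N, 1)
    y <- f1 * as.vector(s)                          # recycles over channels
    e$cache <- list(x = x, a = a, f1 = f1, s = s, amax = amax, cmax = cmax,
                    h_a = h_a, h_m = h_m, s_avg = s_avg, s_max = s_max,
                    spin = spin, d = d)
    y
  }
  e$bwd <- function(dy) {
    cc <- e$cache; d <- cc$d; H <- d[1]; W <- d[2]; N <- d[3]
    HW <- H * W; HWN <- HW * N
    sv <- as.vector(cc$s)
    df1 <- dy * sv
    # spatial attention branch
    ds <- array(rowSums(matrix(dy * cc$f1, HWN, C)), c(H, W, N, 1L))
    dconv <- ds * cc$s * (1 - cc$s)
    e$G$Wsp <- conv2d_small_gradw(cc$spin, dconv, dim(e$P$Wsp))
    dspin <- conv2d_small(dconv, conv2d_flip(e$P$Wsp))      # (H,W,N,2)
    dmt <- matrix(dspin[, , , 1L] / C, HWN, C)
    ix <- cbind(seq_len(HWN), cc$cmax)
    dmt[ix] <- dmt[ix] + as.vector(dspin[, , , 2L])
    dim(dmt) <- d
    df1 <- df1 + dmt
    # channel attention branch
    da <- matrix(colSums(matrix(df1 * cc$x, HW, N * C)), N, C)
    dx <- df1 * bcast(as.vector(cc$a), HW)
    dz <- da * cc$a * (1 - cc$a)                    # (N, C)
    e$G$A2 <- crossprod(dz, cc$h_a + cc$h_m)        # (C, Cr)
    dh <- dz %*% e$P$A2                             # (N, Cr), shared MLP
    dh_a <- dh * (cc$h_a > 0)
    dh_m <- dh * (cc$h_m > 0)
    e$G$A1 <- crossprod(dh_a, cc$s_avg) + crossprod(dh_m, cc$s_max)
    ds_avg <- dh_a %*% e$P$A1                       # (N, C)
    ds_max <- dh_m %*% e$P$A1
    dx <- dx + bcast(as.vector(ds_avg), HW) / HW
    pos <- (seq_len(N * C) - 1L) * HW + cc$amax
    dx[pos] <- dx[pos] + as.vector(ds_max)
    e$cache <- NULL
    dx
  }
  e
}

# Flatten (T=H, W, N, C) to a T-step sequence of (N, W*C) inputs, run an
# LSTM, return the last hidden state (N, U).
layer_lstm <- function(D, U, seed = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "lstm"
  e$P <- list(Wx = glorot_init(D, 4L * U, seed),
              Wh = glorot_init(U, 4L * U, seed + 1L),
              b = rep(c(0, 1, 0, 0), each = U))     # forget-gate bias 1
  e$G <- list()
  gidx <- function(k) ((k - 1L) * U + 1L):(k * U)
  e$fwd <- function(x, train = TRUE) {
    d <- dim(x); TT <- d[1]; N <- d[3]
    h <- matrix(0, N, U); cst <- matrix(0, N, U)
    steps <- vector("list", TT)
    for (t in seq_len(TT)) {
      xt <- aperm(array(x[t, , , ], d[2:4]), c(2, 1, 3))
      dim(xt) <- c(N, d[2] * d[4])                  # (N, D)
      z <- xt %*% e$P$Wx + h %*% e$P$Wh + bcast(e$P$b, N)
      ig <- sigmoid(z[, gidx(1), drop = FALSE])
      fg <- sigmoid(z[, gidx(2), drop = FALSE])
      gg <- tanh(z[, gidx(3), drop = FALSE])
      og <- sigmoid(z[, gidx(4), drop = FALSE])
      c_new <- fg * cst + ig * gg
      tc <- tanh(c_new)
      steps[[t]] <- list(xt = xt, h_prev = h, c_prev = cst, i = ig, f = fg,
                         g = gg, o = og, tc = tc)
      cst <- c_new
      h <- og * tc
    }
    e$cache <- list(steps = steps, d = d)
    h
  }
  e$bwd <- function(dh_last) {
    cc <- e$cache; d <- cc$d; TT <- d[1]; N <- d[3]
    dWx <- matrix(0, nrow(e$P$Wx), ncol(e$P$Wx))
    dWh <- matrix(0, nrow(e$P$Wh), ncol(e$P$Wh))
    db <- numeric(length(e$P$b))
    dx <- array(0, d)
    dh <- dh_last
    dc <- matrix(0, N, U)
    for (t in rev(seq_len(TT))) {
      st <- cc$steps[[t]]
      do <- dh * st$tc * st$o * (1 - st$o)
      dc <- dc + dh * st$o * (1 - st$tc^2)
      di <- dc * st$g * st$i * (1 - st$i)
      dg <- dc * st$i * (1 - st$g^2)
      df <- dc * st$c_prev * st$f * (1 - st$f)
      dz <- cbind(di, df, dg, do)
      dWx <- dWx + crossprod(st$xt, dz)
      dWh <- dWh + crossprod(st$h_prev, dz)
      db <- db + colSums(dz)
      dxt <- dz %*% t(e$P$Wx)                       # (N, D)
      dim(dxt) <- c(N, d[2], d[4])
      dx[t, , , ] <- aperm(dxt, c(2, 1, 3))
      dh <- dz %*% t(e$P$Wh)
      dc <- dc * st$f
    }
    e$G$Wx <- dWx; e$G$Wh <- dWh; e$G$b <- db
    e$cache <- NULL
    dx
  }
  e
}

layer_dense <- function(Din, Dout, seed = 1L) {
  e <- new.env(parent = emptyenv())
  e$type <- "dense"
  e$P <- list(W = glorot_init(Din, Dout, seed), b = numeric(Dout))
  e$G <- list()
  e$fwd <- function(x, train = TRUE) {
    e$cache <- x
    x %*% e$P$W + bcast(e$P$b, nrow(x))
  }
  e$bwd <- function(dy) {
    e$G$W <- crossprod(e$cache, dy)
    e$G$b <- colSums(dy)
    dx <- dy %*% t(e$P$W)
    e$cache <- NULL
    dx
  }
  e
}

# Adam optimizer over a list of layers.
adam_state <- function(layers, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  st <- list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
             m = list(), v = list())
  for (i in seq_along(layers)) {
    st$m[[i]] <- lapply(layers[[i]]$P, function(p) p * 0)
    st$v[[i]] <- lapply(layers[[i]]$P, function(p) p * 0)
  }
  st
}

adam_step <- function(st, layers) {
  st$t <- st$t + 1L
  corr1 <- 1 - st$beta1^st$t
  corr2 <- 1 - st$beta2^st$t
  for (i in seq_along(layers)) {
    L <- layers[[i]]
    for (nm in names(L$P)) {
      g <- L$G[[nm]]
      if (is.null(g)) next
      st$m[[i]][[nm]] <- st$beta1 * st$m[[i]][[nm]] + (1 - st$beta1) * g
      st$v[[i]][[nm]] <- st$beta2 * st$v[[i]][[nm]] + (1 - st$beta2) * g^2
      mhat <- st$m[[i]][[nm]] / corr1
      vhat <- st$v[[i]][[nm]] / corr2
      L$P[[nm]] <- L$P[[nm]] - st$lr * mhat / (sqrt(vhat) + st$eps)
    }
  }
  st
}

# Population-statistic recalibration for batch norm: forward passes made
# between bn_collect_start() and bn_collect_end() normalize with batch
# statistics and accumulate them; the running statistics are then set to
# their momentum-free average. Cures the small-batch drift of
# momentum-tracked statistics before inference.
bn_collect_start <- function(layers) {
  for (l in layers) {
    if (l$type == "batchnorm") {
      l$collecting <- TRUE
      l$acc_mean <- 0; l$acc_var <- 0; l$acc_n <- 0L
    }
  }
  invisible(layers)
}

bn_collect_end <- function(layers) {
  for (l in layers) {
    if (l$type == "batchnorm") {
      if (l$acc_n > 0L) {
        l$run_mean <- l$acc_mean / l$acc_n
        l$run_var <- l$acc_var / l$acc_n
        l$seen <- TRUE
      }
      l$collecting <- FALSE
    }
  }
  invisible(layers)
}

get_weights <- function(layers) {
  lapply(layers, function(l) {
    w <- l$P
    if (l$type == "batchnorm") {
      attr(w, "run_mean") <- l$run_mean
      attr(w, "run_var") <- l$run_var
      attr(w, "seen") <- l$seen
    }
    w
  })
}

set_weights <- function(layers, weights) {
  for (i in seq_along(layers)) {
    attrs <- weights[[i]]
    l <- layers[[i]]
    l$P <- weights[[i]][seq_along(weights[[i]])]
    attributes(l$P) <- list(names = names(weights[[i]]))
    if (l$type == "batchnorm") {
      l$run_mean <- attr(attrs, "run_mean")
      l$run_var <- attr(attrs, "run_var")
      l$seen <- attr(attrs, "seen")
    }
  }
  invisible(layers)
}
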