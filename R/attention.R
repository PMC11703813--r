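#' Initialize CBAM attention parameters
#'
#' Seeded parameters for the channel-attention bottleneck MLP (shared by
#' the average- and max-pooled descriptors) and the spatial-attention
#' convolution.
#'
#' @param channels Number of channels `C` of the feature map.
#' @param reduction Bottleneck reduction ratio (default 16); the hidden
#'   width is `max(1, C %/% reduction)`.
#' @param kernel Odd spatial-convolution kernel size (default 7).
#' @param seed Integer seed.
#' @return A list with `A1` (`Cr x C`), `A2` (`C x Cr`) and `Wsp`
#'   (`kernel x kernel x 2 x 1`).
#' @export
cbam_params <- function(channels, reduction = 16L, kernel = 7L, seed = 1L) {
  if (reduction < 1L || reduction > channels) {
    stop("reduction must satisfy 1 <= reduction <= channels", call. = FALSE)
  }
  if (kernel %% 2L == 0L) stop("kernel must be odd", call. = FALSE)
  cr <- max(1L, channels %/% reduction)
  list(A1 = glorot_init(cr, channels, seed),
       A2 = glorot_init(channels, cr, seed + 1L),
       Wsp = he_init(c(kernel, kernel, 2L, 1L), kernel * kernel * 2,
                     seed + 2L))
}

#' Channel attention weights
#'
#' Global average- and max-pools the feature map over its spatial extent,
#' passes both `C`-vectors through a shared two-layer bottleneck MLP
#' (`C -> C/reduction -> C`, ReLU between), sums, and applies a sigmoid.
#' All weights are therefore strictly in (0, 1).
#'
#' @param fmap Feature map array of dim `(C, H, W)`.
#' @param reduction Bottleneck reduction ratio; ignored when `params` is
#'   supplied.
#' @param params Optional [cbam_params()]; seeded fresh parameters are
#'   drawn when `NULL`.
#' @param seed Seed for fresh parameters.
#' @return Array of dim `(C, 1, 1)` with entries in (0, 1).
#' @export
channel_attention <- function(fmap, reduction = 16L, params = NULL,
                              seed = 1L) {
  d <- dim(fmap)
  stopifnot(length(d) == 3)
  if (is.null(params)) params <- cbam_params(d[1], reduction, seed = seed)
  m <- matrix(fmap, d[1], d[2] * d[3])              # rows = channels
  s_avg <- rowMeans(m)
  s_max <- apply(m, 1, max)
  z <- params$A2 %*% pmax(params$A1 %*% s_avg, 0) +
    params$A2 %*% pmax(params$A1 %*% s_max, 0)
  array(sigmoid(z), c(d[1], 1L, 1L))
}

#' Spatial attention weights
#'
#' Computes channel-wise mean and max maps, stacks them as a 2-channel
#' image, convolves with a single `kernel x kernel` same-padded bias-free
#' filter, and applies a sigmoid.
#'
#' @param fmap Feature map array of dim `(C, H, W)`.
#' @param kernel Odd convolution kernel size; ignored when `params` is
#'   supplied.
#' @param params Optional [cbam_params()].
#' @param seed Seed for fresh parameters.
#' @return Array of dim `(1, H, W)` with entries in (0, 1).
#' @export
spatial_attention <- function(fmap, kernel = 7L, params = NULL, seed = 1L) {
  d <- dim(fmap)
  stopifnot(length(d) == 3)
  if (kernel %% 2L == 0L) stop("kernel must be odd", call. = FALSE)
  if (is.null(params)) params <- cbam_params(d[1], 1L, kernel, seed = seed)
  m <- matrix(fmap, d[1], d[2] * d[3])
  sp_mean <- colMeans(m)
  sp_max <- apply(m, 2, max)
  spin <- array(0, c(d[2], d[3], 1L, 2L))           # (H, W, N = 1, C = 2)
  spin[, , 1L, 1L] <- sp_mean
  spin[, , 1L, 2L] <- sp_max
  y <- conv2d_small(spin, params$Wsp)
  array(sigmoid(y[, , 1L, 1L]), c(1L, d[2], d[3]))
}

#' Apply attention maps to a feature map
#'
#' `F1 = channel_weights * F` (broadcast over H, W) followed by
#' `F2 = spatial_weights * F1` (broadcast over C). Output shape equals
#' input shape, and with weights in (0, 1) the operation is a contraction
#' on nonnegative maps.
#'
#' @param fmap Feature map array of dim `(C, H, W)`.
#' @param maps List with `channel_weights` (`C x 1 x 1`) and
#'   `spatial_weights` (`1 x H x W`); either may be `NULL` to skip that
#'   stage.
#' @return Array of dim `(C, H, W)`.
#' @export
apply_cbam <- function(fmap, maps) {
  d <- dim(fmap)
  stopifnot(length(d) == 3)
  out <- fmap
  if (!is.null(maps$channel_weights)) {
    cw <- maps$channel_weights
    if (!identical(dim(cw)[1], d[1])) {
      stop("channel_weights must have C rows matching the feature map",
           call. = FALSE)
    }
    out <- out * as.vector(cw)                      # recycles over (H, W)
  }
  if (!is.null(maps$spatial_weights)) {
    sw <- maps$spatial_weights
    if (!identical(as.integer(dim(sw)[2:3]), as.integer(d[2:3]))) {
      stop("spatial_weights must match the feature map's H x W", call. = FALSE)
    }
    out <- out * rep(as.vector(sw[1L, , ]), each = d[1])
  }
  out
}

#' One full CBAM pass over a channels-first feature map
#'
#' Convenience composition: channel attention, multiply, spatial attention
#' on the reweighted map, multiply.
#'
#' @inheritParams channel_attention
#' @param kernel Spatial kernel size.
#' @return List with `output` (`C x H x W`), `channel_weights` and
#'   `spatial_weights`.
#' @export
cbam_forward <- function(fmap, reduction = 16L, kernel = 7L, params = NULL,
                         seed = 1L) {
  d <- dim(fmap)
  if (is.null(params)) params <- cbam_params(d[1], reduction, kernel, seed)
  cw <- channel_attention(fmap, params = params)
  f1 <- apply_cbam(fmap, list(channel_weights = cw))
  sw <- spatial_attention(f1, params = params)
  f2 <- apply_cbam(f1, list(spatial_weights = sw))
  list(output = f2, channel_weights = cw, spatial_weights = sw)
}
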