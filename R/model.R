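#' Configuration of the CBAM-LSTM classifier
#'
#' Defaults follow the published training recipe: three convolutional
#' blocks with 64/128/256 3x3 filters, LeakyReLU, batch normalization,
#' CBAM, 2x2 max pooling and dropout; an LSTM over the 16 remaining time
#' steps; a dense LeakyReLU layer and a sigmoid output unit; Adam with
#' learning rate 0.001, batch size 64, up to 300 epochs with early
#' stopping, classification threshold 0.5.
#'
#' @param conv_filters Integer vector of filters per block.
#' @param leaky_slope Negative-slope coefficient of LeakyReLU.
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param cbam_reduction Channel-attention bottleneck ratio.
#' @param cbam_kernel Odd spatial-attention kernel size.
#' @param lstm_units LSTM hidden units.
#' @param dense_units Units of the penultimate dense layer.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (best weights restored).
#' @param threshold Probability threshold; `p >= threshold` is labelled
#'   abnormal.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `model_config` list.
#' @export
model_config <- function(conv_filters = c(64L, 128L, 256L),
                         leaky_slope = 0.01, dropout_rate = 0.3,
                         cbam_reduction = 16L, cbam_kernel = 7L,
                         lstm_units = 128L, dense_units = 64L,
                         learning_rate = 0.001, batch_size = 64L,
                         max_epochs = 300L, early_stop_patience = 10L,
                         threshold = 0.5, seed = 1L) {
  stopifnot(length(conv_filters) >= 1, all(conv_filters >= 1),
            dropout_rate >= 0, dropout_rate < 1,
            cbam_kernel %% 2 == 1, threshold > 0, threshold < 1,
            learning_rate > 0, batch_size >= 1, max_epochs >= 1)
  structure(list(conv_filters = as.integer(conv_filters),
                 leaky_slope = leaky_slope, dropout_rate = dropout_rate,
                 cbam_reduction = as.integer(cbam_reduction),
                 cbam_kernel = as.integer(cbam_kernel),
                 lstm_units = as.integer(lstm_units),
                 dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 threshold = threshold, seed = as.integer(seed)),
            class = "model_config")
}

#' Binary cross-entropy loss
#'
#' Mean negative log-likelihood
#' `-(1/N) * sum(y*log(p) + (1-y)*log(1-p))` with predictions clipped to
#' `[1e-7, 1 - 1e-7]`.
#'
#' @param y Numeric vector of labels in \{0, 1\}.
#' @param yhat Numeric vector of predicted probabilities.
#' @return Nonnegative scalar loss.
#' @export
binary_cross_entropy <- function(y, yhat) {
  if (length(y) != length(yhat)) {
    stop("labels and predictions differ in length", call. = FALSE)
  }
  p <- pmin(pmax(yhat, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Assemble an untrained CBAM-LSTM classifier
#'
#' Builds the layer stack for inputs of shape `(time, feature, 1)`:
#' per block `conv 3x3 -> LeakyReLU -> batch norm -> CBAM -> max pool 2x2
#' -> dropout`, then an LSTM over the remaining time steps (last hidden
#' state), a dense LeakyReLU layer with dropout, and a single-logit output
#' (sigmoid applied at prediction time). Initialization is deterministic
#' given `config$seed`.
#'
#' @param config A [model_config()].
#' @param input_shape Integer vector `(time, feature, channel)`; default
#'   `c(128, 141, 1)`, the fused-feature shape.
#' @return A `cbam_lstm` model object.
#' @export
build_model <- function(config = model_config(),
                        input_shape = c(128L, 141L, 1L)) {
  stopifnot(inherits(config, "model_config"), length(input_shape) == 3)
  H <- as.integer(input_shape[1]); W <- as.integer(input_shape[2])
  C <- as.integer(input_shape[3])
  seeds <- derive_seeds(config$seed, 4L * length(config$conv_filters) + 4L)
  layers <- list()
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }
  in_c <- C
  for (f in config$conv_filters) {
    red <- min(config$cbam_reduction, f)
    layers <- c(layers, list(
      layer_conv2d(in_c, f, k = 3L, seed = nxt()),
      layer_leaky_relu(config$leaky_slope),
      layer_batchnorm(f),
      layer_cbam(f, reduction = red, kernel = config$cbam_kernel,
                 seed = nxt()),
      layer_maxpool2(),
      layer_dropout(config$dropout_rate)
    ))
    in_c <- f
    H <- H %/% 2L; W <- W %/% 2L
    if (H < 1L || W < 1L) {
      stop("input shape too small for ", length(config$conv_filters),
           " pooling stages", call. = FALSE)
    }
  }
  layers <- c(layers, list(
    layer_lstm(W * in_c, config$lstm_units, seed = nxt()),
    layer_dense(config$lstm_units, config$dense_units, seed = nxt()),
    layer_leaky_relu(config$leaky_slope),
    layer_dropout(config$dropout_rate),
    layer_dense(config$dense_units, 1L, seed = nxt())
  ))
  structure(list(layers = layers, config = config,
                 input_shape = as.integer(input_shape),
                 seq_shape = c(H, W, in_c), trained = FALSE),
            class = "cbam_lstm")
}

#' @export
print.cbam_lstm <- function(x, ...) {
  np <- sum(vapply(x$layers,
                   function(l) sum(vapply(l$P, length, numeric(1))),
                   numeric(1)))
  cat(sprintf("<cbam_lstm> input (%s), %d layers, %d parameters, %s\n",
              paste(x$input_shape, collapse = ","), length(x$layers), np,
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Forward pass on a batch array (H, W, C, N); returns logits (N).
model_forward <- function(model, x, train = FALSE) {
  for (l in model$layers) x <- l$fwd(x, train = train)
  as.vector(x)
}

model_backward <- function(model, dlogit) {
  dy <- matrix(dlogit, ncol = 1L)
  for (l in rev(model$layers)) dy <- l$bwd(dy)
  invisible(dy)
}

# Stack a list of (H, W, 1) feature arrays into an (H, W, N, C = 1)
# batch (the engine's channels-last layout; for single-channel inputs the
# two orderings coincide elementwise).
stack_features <- function(features) {
  d <- dim(features[[1]])
  array(unlist(features, use.names = FALSE),
        c(d[1], d[2], length(features), d[3]))
}

label_to01 <- function(labels) as.numeric(labels == "abnormal")

#' Train the CBAM-LSTM classifier
#'
#' Minimizes binary cross-entropy with Adam on seeded shuffled
#' minibatches, evaluating the validation set each epoch. Early stopping
#' monitors validation loss with the configured patience and restores the
#' best-validation weights. Fully deterministic given `config$seed`.
#'
#' @param model An untrained [build_model()] object.
#' @param train_features,val_features Lists of `(time, feature, 1)`
#'   arrays (e.g. the `feature` column of [featurize_dataset()]).
#' @param train_labels,val_labels Character labels
#'   (`"normal"`/`"abnormal"`) or 0/1 numerics (1 = abnormal).
#' @param verbose Print a line per epoch.
#' @return The model, with `$trace` (a tibble of per-epoch train/val loss
#'   and accuracy, class `training_trace`) and `$trained = TRUE`.
#' @export
train_model <- function(model, train_features, train_labels,
                        val_features, val_labels, verbose = FALSE) {
  stopifnot(inherits(model, "cbam_lstm"))
  cfg <- model$config
  y_tr <- if (is.character(train_labels)) label_to01(train_labels) else as.numeric(train_labels)
  y_va <- if (is.character(val_labels)) label_to01(val_labels) else as.numeric(val_labels)
  if (length(unique(y_tr)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  if (length(unique(y_va)) < 2L) {
    stop("validation set must contain both classes", call. = FALSE)
  }
  n <- length(train_features)
  st <- adam_state(model$layers, lr = cfg$learning_rate)
  best_loss <- Inf; best_w <- NULL; best_epoch <- 0L; wait <- 0L
  trace <- list()
  with_seed(cfg$seed + 10000L, {
    for (epoch in seq_len(cfg$max_epochs)) {
      idx <- sample.int(n)
      batches <- split(idx, ceiling(seq_along(idx) / cfg$batch_size))
      ep_loss <- 0; ep_correct <- 0
      for (b in batches) {
        xb <- stack_features(train_features[b])
        yb <- y_tr[b]
        logit <- model_forward(model, xb, train = TRUE)
        p <- sigmoid(logit)
        ep_loss <- ep_loss + binary_cross_entropy(yb, p) * length(b)
        ep_correct <- ep_correct + sum((p >= cfg$threshold) == (yb == 1))
        model_backward(model, (p - yb) / length(b))
        st <- adam_step(st, model$layers)
      }
      va <- evaluate_pass(model, val_features, y_va, cfg)
      trace[[epoch]] <- c(epoch = epoch, train_loss = ep_loss / n,
                          val_loss = va$loss, train_accuracy = ep_correct / n,
                          val_accuracy = va$accuracy)
      if (verbose) {
        message(sprintf("epoch %3d  train %.4f/%.3f  val %.4f/%.3f",
                        epoch, ep_loss / n, ep_correct / n, va$loss,
                        va$accuracy))
      }
      if (va$loss < best_loss - 1e-6) {
        best_loss <- va$loss; best_epoch <- epoch; wait <- 0L
        best_w <- get_weights(model$layers)
      } else {
        wait <- wait + 1L
        if (wait >= cfg$early_stop_patience) break
      }
    }
  })
  if (!is.null(best_w)) set_weights(model$layers, best_w)
  # replace momentum-tracked batch-norm statistics with their
  # population estimate under the final weights (one pass, no updates)
  bn_collect_start(model$layers)
  i <- 1L
  while (i <= n) {
    j <- min(i + cfg$batch_size - 1L, n)
    model_forward(model, stack_features(train_features[i:j]), train = FALSE)
    i <- j + 1L
  }
  bn_collect_end(model$layers)
  tr <- tibble::as_tibble(do.call(rbind, trace))
  tr$epoch <- as.integer(tr$epoch)
  class(tr) <- c("training_trace", class(tr))
  attr(tr, "stopped_epoch") <- nrow(tr)
  attr(tr, "best_epoch") <- best_epoch
  model$trace <- tr
  model$trained <- TRUE
  model
}

evaluate_pass <- function(model, features, y, cfg) {
  p <- predict_prob(model, features, batch_size = cfg$batch_size)
  list(loss = binary_cross_entropy(y, p),
       accuracy = mean((p >= cfg$threshold) == (y == 1)))
}

predict_prob <- function(model, features, batch_size = 64L) {
  n <- length(features)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    xb <- stack_features(features[i:j])
    out[i:j] <- sigmoid(model_forward(model, xb, train = FALSE))
    i <- j + 1L
  }
  out
}

#' Predict labels and probabilities
#'
#' Dropout is disabled and batch normalization uses running statistics, so
#' repeated calls are bit-identical and independent of batch ordering. A
#' sample is labelled abnormal when its probability is greater than or
#' equal to the threshold.
#'
#' @param object A trained `cbam_lstm` model.
#' @param features List of `(time, feature, 1)` arrays, or a featurized
#'   manifest tibble with a `feature` column.
#' @param threshold Probability threshold (default from the model config).
#' @param ... Unused.
#' @return A tibble with columns `probability` and `predicted`
#'   (`"normal"`/`"abnormal"`), plus `id` and `label` when a manifest was
#'   given.
#' @export
predict.cbam_lstm <- function(object, features,
                              threshold = object$config$threshold, ...) {
  if (!isTRUE(object$trained)) {
    stop("model has not been trained; call train_model() first", call. = FALSE)
  }
  man <- NULL
  if (tibble::is_tibble(features)) {
    man <- features
    features <- man$feature
  }
  p <- predict_prob(object, features, batch_size = object$config$batch_size)
  out <- tibble::tibble(probability = p,
                        predicted = ifelse(p >= threshold, "abnormal", "normal"))
  if (!is.null(man)) {
    out <- tibble::tibble(id = man$id, label = man$label, out)
  }
  out
}

#' Save / load a CBAM-LSTM model
#'
#' Serializes the configuration, input shape and all weights (including
#' batch-norm running statistics); the reloaded model reproduces
#' probabilities bit-identically.
#'
#' @param model A `cbam_lstm` model.
#' @param path File path (RDS).
#' @return `path` invisibly for `save_model()`; the model for
#'   `load_model()`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cbam_lstm"))
  saveRDS(list(config = model$config, input_shape = model$input_shape,
               weights = get_weights(model$layers), trained = model$trained,
               trace = model$trace), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  model <- build_model(obj$config, obj$input_shape)
  set_weights(model$layers, obj$weights)
  model$trained <- obj$trained
  model$trace <- obj$trace
  model
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a training trace
#'
#' @param x A `training_trace` tibble (from `model$trace`).
#' @param ... Unused.
#' @return Long tibble with columns `epoch`, `metric`, `set`, `value`.
#' @method tidy training_trace
#' @export
tidy.training_trace <- function(x, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(unclass(x)), -"epoch",
                              names_to = "series", values_to = "value")
  parts <- strsplit(long$series, "_")
  long$set <- vapply(parts, `[`, "", 1L)
  long$metric <- vapply(parts, `[`, "", 2L)
  long[, c("epoch", "metric", "set", "value")]
}

#' @rdname tidy.training_trace
#' @method glance training_trace
#' @export
glance.training_trace <- function(x, ...) {
  tibble::tibble(epochs = nrow(x),
                 best_epoch = attr(x, "best_epoch"),
                 final_train_loss = x$train_loss[nrow(x)],
                 final_val_loss = x$val_loss[nrow(x)],
                 best_val_loss = min(x$val_loss),
                 final_val_accuracy = x$val_accuracy[nrow(x)])
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a training trace
#'
#' Loss and accuracy per epoch for the training and validation sets.
#'
#' @param object A `training_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom rlang .data
#' @method autoplot training_trace
#' @export
autoplot.training_trace <- function(object, ...) {
  long <- tidy.training_trace(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
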