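#' Specify a classifier architecture and its training configuration
#'
#' Three families are supported:
#' \describe{
#'   \item{`cnn_standard`}{0-3 blocks of convolution (kernel size 3) +
#'     rectifier + max-pooling + 50\% dropout, then dense layers of 1000 and
#'     500 rectified units and a softmax output. Filter counts follow
#'     `32 * 2^i` per block (64, 128, 256 with the default indexing).
#'     Convolutions are 1D for k-mer input and 2D for curve input. Trained
#'     with Adam. Zero blocks gives a dense-only network.}
#'   \item{`cnn_improved`}{5 convolution layers interleaved with batch
#'     normalization, Leaky ReLU and max-pooling; additive Gaussian noise
#'     after every 2 convolution layers; 20\% dropout after the last; dense
#'     layers of 128 and 64 units; softmax. Trained with AMSGrad at learning
#'     rate 0.0005.}
#'   \item{`bilstm`}{two bidirectional LSTM layers (50, 100 or 150 nodes)
#'     alternating with 20\% dropout, a dense layer and a softmax output;
#'     consumes variable-length k-mer encodings without padding.}
#' }
#'
#' @param family `"cnn_standard"`, `"cnn_improved"` or `"bilstm"`.
#' @param input_shape Integer vector: (positions, channels) for 1D input,
#'   (side, side, channels) for 2D input, or just the channel count for the
#'   variable-length `bilstm` family.
#' @param n_classes Number of classes C (>= 2).
#' @param n_conv_layers Number of convolution blocks, 0-3 (`cnn_standard`).
#' @param rnn_nodes LSTM units per direction (`bilstm`), one of 50/100/150
#'   in the reference experiments (any positive integer is accepted).
#' @param filter_base_index Index of the first convolution block in the
#'   `32 * 2^i` filter rule; the default 1 yields 64, 128, 256.
#' @param optimizer `"adam"` or `"amsgrad"`; default depends on the family.
#' @param learning_rate Step size; defaults to 1e-3 (Adam) or 5e-4 (AMSGrad).
#' @param batch_size,epochs,patience Minibatch size, maximum epochs, and
#'   early-stopping patience on validation loss.
#' @param lr_decay Optional per-epoch multiplicative learning-rate decay
#'   (1 = constant rate).
#' @param seed Integer seed for weight initialization and training.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(family = c("cnn_standard", "cnn_improved", "bilstm"),
                       input_shape, n_classes,
                       n_conv_layers = 3, rnn_nodes = 100,
                       filter_base_index = 1,
                       optimizer = NULL, learning_rate = NULL,
                       batch_size = 128, epochs = 100, patience = 10,
                       lr_decay = 1, seed = 1L) {
  family <- match.arg(family)
  if (n_classes < 2) abort("n_classes must be >= 2")
  if (family == "cnn_standard" && !(n_conv_layers %in% 0:3)) {
    abort("n_conv_layers must be 0, 1, 2 or 3 for the standard CNN")
  }
  if (is.null(optimizer)) {
    optimizer <- if (family == "cnn_improved") "amsgrad" else "adam"
  }
  if (is.null(learning_rate)) {
    learning_rate <- if (family == "cnn_improved") 5e-4 else 1e-3
  }
  structure(
    list(family = family, input_shape = as.integer(input_shape),
         n_classes = as.integer(n_classes),
         n_conv_layers = as.integer(n_conv_layers),
         rnn_nodes = as.integer(rnn_nodes),
         filter_base_index = as.integer(filter_base_index),
         optimizer = optimizer, learning_rate = learning_rate,
         batch_size = as.integer(batch_size), epochs = as.integer(epochs),
         patience = as.integer(patience), lr_decay = lr_decay,
         seed = as.integer(seed)),
    class = "model_spec"
  )
}

new_rna_model <- function(layers, spec) {
  structure(list(layers = layers, spec = spec), class = "rna_model")
}

#' @export
print.rna_model <- function(x, ...) {
  cat("<rna_model> ", x$spec$family, ": ",
      paste(vapply(x$layers, function(l) l$type, character(1)), collapse = " -> "),
      "\n", sep = "")
  invisible(x)
}

#' Layer-by-layer summary of a model
#'
#' @param model An `rna_model` or `trained_classifier`.
#' @return A tibble with one row per layer: `type`, `units` (filters, dense
#'   width or LSTM units where applicable) and `n_params`.
#' @export
model_layers <- function(model) {
  if (inherits(model, "trained_classifier")) model <- model$model
  tibble::tibble(
    type = vapply(model$layers, function(l) l$type, character(1)),
    units = vapply(model$layers, function(l) {
      if (!is.null(l$W)) ncol(l$W)
      else if (!is.null(l$gamma)) length(l$gamma)
      else NA_integer_
    }, numeric(1)),
    n_params = vapply(model$layers, function(l) {
      pn <- intersect(names(l),
                      c("W", "b", "gamma", "beta", "U", "W_r", "U_r", "b_r"))
      sum(vapply(pn, function(p) length(l[[p]]), numeric(1)))
    }, numeric(1))
  )
}

#' Build the standard convolutional classifier
#'
#' `n_conv_layers` blocks of convolution (kernel 3, "same" zero padding) +
#' ReLU + max-pooling (window 2) + 50\% dropout, followed by flatten, dense
#' layers of 1000 and 500 rectified units, and a linear output of width
#' `n_classes` (softmax applied by the loss / [predict_proba()]). The i-th
#' block has `32 * 2^i` filters. Convolution dimensionality follows the
#' input shape: (positions, channels) gives 1D, (side, side, channels) 2D.
#'
#' @param spec A [model_spec()] with `family = "cnn_standard"`.
#' @return An untrained `rna_model`.
#' @export
build_standard_cnn <- function(spec) {
  if (spec$family != "cnn_standard") abort("spec$family must be 'cnn_standard'")
  is2d <- length(spec$input_shape) == 3
  if (!is2d && length(spec$input_shape) != 2) {
    abort("input_shape must be (positions, channels) or (side, side, channels)")
  }
  set.seed(spec$seed)
  layers <- list()
  Cin <- spec$input_shape[length(spec$input_shape)]
  spatial <- spec$input_shape[-length(spec$input_shape)]
  for (i in seq_len(spec$n_conv_layers)) {
    f <- 32L * 2L^(spec$filter_base_index + i - 1L)
    ksz <- if (is2d) 9L else 3L
    layers <- c(layers, list(
      nn_layer(if (is2d) "conv2d" else "conv1d",
               W = he_init(ksz * Cin, c(ksz * Cin, f)), b = numeric(f)),
      nn_layer("relu"),
      nn_layer(if (is2d) "maxpool2d" else "maxpool1d"),
      nn_layer("dropout", rate = 0.5)
    ))
    Cin <- f
    spatial <- pmax(spatial %/% 2L, pmin(spatial, 1L))
  }
  flat <- prod(spatial) * Cin
  layers <- c(layers, list(
    nn_layer("flatten"),
    nn_layer("dense", W = he_init(flat, c(flat, 1000L)), b = numeric(1000)),
    nn_layer("relu"),
    nn_layer("dense", W = he_init(1000, c(1000L, 500L)), b = numeric(500)),
    nn_layer("relu"),
    nn_layer("dense", W = he_init(500, c(500L, spec$n_classes)),
             b = numeric(spec$n_classes))
  ))
  new_rna_model(layers, spec)
}

#' Build the improved 5-layer convolutional classifier
#'
#' Five convolution layers (filters 32, 32, 64, 64, 128) each followed by
#' batch normalization, Leaky ReLU and max-pooling; additive Gaussian noise
#' (sd 0.1) after blocks 2 and 4; 20\% dropout after the last block; dense
#' layers of 128 and 64 units; linear output of width `n_classes`. Intended
#' to be trained with AMSGrad at learning rate 0.0005. Pooling becomes a
#' no-op once a spatial dimension reaches 1.
#'
#' @param spec A [model_spec()] with `family = "cnn_improved"`.
#' @return An untrained `rna_model`.
#' @export
build_improved_cnn <- function(spec) {
  if (spec$family != "cnn_improved") abort("spec$family must be 'cnn_improved'")
  is2d <- length(spec$input_shape) == 3
  set.seed(spec$seed)
  filters <- c(32L, 32L, 64L, 64L, 128L)
  layers <- list()
  Cin <- spec$input_shape[length(spec$input_shape)]
  spatial <- spec$input_shape[-length(spec$input_shape)]
  for (i in seq_along(filters)) {
    f <- filters[i]
    ksz <- if (is2d) 9L else 3L
    layers <- c(layers, list(
      nn_layer(if (is2d) "conv2d" else "conv1d",
               W = he_init(ksz * Cin, c(ksz * Cin, f)), b = numeric(f)),
      nn_layer("batchnorm", gamma = rep(1, f), beta = numeric(f),
               running_mean = numeric(f), running_var = rep(1, f),
               momentum = 0.99, eps = 1e-3),
      nn_layer("leaky_relu", alpha = 0.3),
      nn_layer(if (is2d) "maxpool2d" else "maxpool1d")
    ))
    if (i %% 2 == 0) layers <- c(layers, list(nn_layer("gaussian_noise", sd = 0.1)))
    Cin <- f
    spatial <- pmax(spatial %/% 2L, pmin(spatial, 1L))
  }
  layers <- c(layers, list(nn_layer("dropout", rate = 0.2)))
  flat <- prod(spatial) * Cin
  layers <- c(layers, list(
    nn_layer("flatten"),
    nn_layer("dense", W = he_init(flat, c(flat, 128L)), b = numeric(128)),
    nn_layer("relu"),
    nn_layer("dense", W = he_init(128, c(128L, 64L)), b = numeric(64)),
    nn_layer("relu"),
    nn_layer("dense", W = he_init(64, c(64L, spec$n_classes)),
             b = numeric(spec$n_classes))
  ))
  new_rna_model(layers, spec)
}

#' Build the bidirectional LSTM classifier
#'
#' Two bidirectional LSTM layers of `rnn_nodes` units per direction,
#' alternating with 20\% dropout, then a dense softmax output. Consumes
#' variable-length k-mer encodings ([encode_kmer_ragged()]); fixed-grid
#' curve encodings are rejected.
#'
#' @param spec A [model_spec()] with `family = "bilstm"`; `input_shape` is
#'   the channel count of the k-mer encoding (4^k).
#' @return An untrained `rna_model`.
#' @export
build_bilstm <- function(spec) {
  if (spec$family != "bilstm") abort("spec$family must be 'bilstm'")
  if (length(spec$input_shape) != 1) {
    abort("bilstm takes variable-length 1D input; curve encodings are not supported")
  }
  set.seed(spec$seed)
  u <- spec$rnn_nodes
  l1 <- bilstm_init(spec$input_shape, u)
  l1$return_sequences <- TRUE
  l2 <- bilstm_init(2L * u, u)
  layers <- list(
    l1,
    nn_layer("dropout", rate = 0.2),
    l2,
    nn_layer("dropout", rate = 0.2),
    nn_layer("dense", W = he_init(2 * u, c(2L * u, spec$n_classes)),
             b = numeric(spec$n_classes))
  )
  new_rna_model(layers, spec)
}

#' Build any model family from its spec
#'
#' @param spec A [model_spec()].
#' @return An untrained `rna_model`.
#' @export
build_model <- function(spec) {
  switch(spec$family,
    cnn_standard = build_standard_cnn(spec),
    cnn_improved = build_improved_cnn(spec),
    bilstm = build_bilstm(spec)
  )
}

as_model_input <- function(x) {
  if (inherits(x, "encoded_batch")) x$array
  else if (inherits(x, "ragged_batch")) x$seqs
  else x
}

check_input_shape <- function(model, X) {
  shape <- model$spec$input_shape
  if (is.list(X) && !is.array(X)) {
    if (ncol(X[[1]]) != shape[1]) {
      abort(paste0("Ragged input has ", ncol(X[[1]]), " channels; model expects ",
                   shape[1]))
    }
  } else {
    got <- dim(X)[-1]
    if (length(got) != length(shape) || any(got != shape)) {
      abort(paste0("Input shape (", paste(got, collapse = ", "),
                   ") does not match model input_shape (",
                   paste(shape, collapse = ", "), ")"))
    }
  }
}

#' Train a classifier on encoded sequences
#'
#' Optimizes categorical cross-entropy with the spec's optimizer (Adam for
#' the standard CNN and BiLSTM, AMSGrad for the improved CNN) using
#' minibatch gradient descent, monitoring validation loss for early
#' stopping; the weights of the best validation epoch are restored. Class
#' order is the lexicographic sort of the training labels, and one-hot
#' targets follow it. Fully reproducible under the spec's seed.
#'
#' @param model An untrained `rna_model`.
#' @param x_train,x_val `encoded_batch` / `ragged_batch` inputs.
#' @param y_train,y_val Character label vectors aligned with the batches.
#' @param verbose Print per-epoch progress?
#' @return A `trained_classifier`: the fitted model, its class order, the
#'   per-epoch training history (a tibble via `tidy()`), and the spec.
#' @export
train_classifier <- function(model, x_train, y_train, x_val, y_val,
                             verbose = FALSE) {
  spec <- model$spec
  classes <- sort(unique(as.character(y_train)))
  if (length(classes) != spec$n_classes) {
    abort(paste0("Training labels contain ", length(classes),
                 " classes but the model was built for ", spec$n_classes))
  }
  missing_cl <- setdiff(unique(as.character(y_val)), classes)
  if (length(missing_cl) > 0) {
    abort(paste0("Validation classes absent from training: ",
                 paste(missing_cl, collapse = ", ")))
  }
  Xtr <- as_model_input(x_train)
  Xva <- as_model_input(x_val)
  check_input_shape(model, Xtr)
  n_val <- if (is.list(Xva) && !is.array(Xva)) length(Xva) else dim(Xva)[1]
  if (n_val == 0) abort("Validation set is empty")
  config <- list(optimizer = spec$optimizer, learning_rate = spec$learning_rate,
                 batch_size = spec$batch_size, epochs = spec$epochs,
                 patience = spec$patience, lr_decay = spec$lr_decay,
                 seed = spec$seed, verbose = verbose)
  fit <- nn_fit(model, Xtr, match(y_train, classes), Xva, match(y_val, classes),
                spec$n_classes, config)
  structure(list(model = fit$model, classes = classes, history = fit$history,
                 spec = spec),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  h <- x$history
  cat("<trained_classifier> ", x$spec$family, ", ", length(x$classes),
      " classes, ", nrow(h), " epochs (best val_loss ",
      signif(min(h$val_loss), 4), ")\n", sep = "")
  invisible(x)
}

#' @export
tidy.trained_classifier <- function(x, ...) x$history

#' @export
glance.trained_classifier <- function(x, ...) {
  h <- x$history
  best <- which.min(h$val_loss)
  tibble::tibble(
    family = x$spec$family, n_classes = length(x$classes),
    epochs_run = nrow(h),
    best_epoch = best,
    val_loss = h$val_loss[best], val_accuracy = h$val_accuracy[best],
    n_params = sum(model_layers(x)$n_params)
  )
}

#' @export
autoplot.trained_classifier <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, -"epoch",
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "Training history", y = NULL) +
    ggplot2::theme_minimal()
}

#' Class-probability predictions
#'
#' Runs the trained network in deterministic evaluation mode (dropout and
#' noise off, batch normalization on running statistics) and applies the
#' softmax. Each row sums to 1; the predicted label is the class of the
#' maximal entry, ties broken by the lowest class index.
#'
#' @param classifier A `trained_classifier`.
#' @param x An `encoded_batch` / `ragged_batch` matching the model input.
#' @param batch_size Forward-pass batch size.
#' @return An n x C matrix of probabilities with classes as column names.
#' @export
predict_proba <- function(classifier, x, batch_size = 256) {
  X <- as_model_input(x)
  check_input_shape(classifier$model, X)
  n <- if (is.list(X) && !is.array(X)) length(X) else dim(X)[1]
  out <- matrix(0, n, length(classifier$classes),
                dimnames = list(NULL, classifier$classes))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- nn_forward(classifier$model, slice_batch(X, idx), mode = "eval")
    out[idx, ] <- nn_softmax(fw$out)
  }
  out
}

#' Hard label predictions
#'
#' @inheritParams predict_proba
#' @return Character vector of predicted class labels.
#' @export
predict_classes <- function(classifier, x, batch_size = 256) {
  p <- predict_proba(classifier, x, batch_size)
  classifier$classes[max.col(p, ties.method = "first")]
}
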