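# Minimal dense/convolutional/recurrent network engine.
#
# No deep-learning framework is assumed: convolutions are realised as
# im2col + BLAS matrix products, with hand-written backward passes and an
# Adam/AMSGrad optimizer. Arrays are batch-first with channels last:
# (n, L, C) for 1D and (n, H, W, C) for 2D inputs. Three execution modes:
#   train - dropout + Gaussian noise active, batch-norm uses batch stats
#   eval  - all stochastic layers off, batch-norm uses running stats
#   mc    - Monte Carlo Dropout: ONLY dropout active, batch-norm running stats

nn_layer <- function(type, ...) {
  c(list(type = type), list(...))
}

he_init <- function(fan_in, dims) {
  array(rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

# ---- conv1d (kernel 3, stride 1, zero "same" padding) ----

conv1d_im2col <- function(X) {
  d <- dim(X)
  cpp_im2col1d(X, d[1], d[2], d[3])
}

conv1d_forward <- function(layer, X) {
  d <- dim(X); n <- d[1]; L <- d[2]
  M <- conv1d_im2col(X)
  Y <- M %*% layer$W
  cpp_add_bias(Y, layer$b)
  list(Y = array(Y, c(n, L, ncol(layer$W))), cache = list(M = M, dims = d))
}

conv1d_backward <- function(layer, cache, dY) {
  d <- cache$dims; n <- d[1]; L <- d[2]; C <- d[3]
  dYm <- matrix(dY, n * L, dim(dY)[3])
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, layer$W)
  list(dX = cpp_col2im1d(dM, n, L, C), grads = list(W = dW, b = db))
}

# ---- conv2d (3x3, stride 1, zero "same" padding) ----

conv2d_im2col <- function(X) {
  d <- dim(X)
  cpp_im2col2d(X, d[1], d[2], d[3], d[4])
}

conv2d_forward <- function(layer, X) {
  d <- dim(X)
  M <- conv2d_im2col(X)
  Y <- M %*% layer$W
  cpp_add_bias(Y, layer$b)
  list(Y = array(Y, c(d[1], d[2], d[3], ncol(layer$W))),
       cache = list(M = M, dims = d))
}

conv2d_backward <- function(layer, cache, dY) {
  d <- cache$dims; n <- d[1]; H <- d[2]; W <- d[3]; C <- d[4]
  dYm <- matrix(dY, n * H * W, dim(dY)[4])
  dW <- crossprod(cache$M, dYm)
  db <- colSums(dYm)
  dM <- tcrossprod(dYm, layer$W)
  list(dX = cpp_col2im2d(dM, n, H, W, C), grads = list(W = dW, b = db))
}

# ---- max pooling, window 2 stride 2; identity when the dim is too small ----

maxpool1d_forward <- function(X) {
  d <- dim(X); L <- d[2]
  if (L < 2) return(list(Y = X, cache = list(identity = TRUE)))
  mp <- cpp_maxpool1d(X, d[1], L, d[3])
  list(Y = mp$Y, cache = list(identity = FALSE, maskA = mp$maskA, dims = d))
}

maxpool1d_backward <- function(cache, dY) {
  if (cache$identity) return(dY)
  d <- cache$dims
  cpp_maxpool1d_bwd(dY, cache$maskA, d[1], d[2], d[3])
}

maxpool2d_forward <- function(X) {
  d <- dim(X); H <- d[2]; W <- d[3]
  if (H < 2 || W < 2) return(list(Y = X, cache = list(identity = TRUE)))
  mp <- cpp_maxpool2d(X, d[1], H, W, d[4])
  list(Y = mp$Y, cache = list(identity = FALSE, arg = mp$arg, dims = d))
}

maxpool2d_backward <- function(cache, dY) {
  if (cache$identity) return(dY)
  d <- cache$dims
  cpp_maxpool2d_bwd(dY, cache$arg, d[1], d[2], d[3], d[4])
}

# ---- batch normalization over the trailing channel axis ----

as_channel_matrix <- function(X) {
  d <- dim(X)
  C <- d[length(d)]
  matrix(X, prod(d) / C, C)
}

batchnorm_forward <- function(layer, X, mode) {
  d <- dim(X)
  Xm <- as_channel_matrix(X)
  if (mode == "train") {
    mu <- colMeans(Xm)
    v <- colMeans(sweep(Xm, 2, mu)^2)
    layer$running_mean <- layer$momentum * layer$running_mean + (1 - layer$momentum) * mu
    layer$running_var <- layer$momentum * layer$running_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$running_mean
    v <- layer$running_var
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(sweep(Xm, 2, mu), 2, inv_sd, "*")
  Y <- sweep(sweep(xhat, 2, layer$gamma, "*"), 2, layer$beta, "+")
  list(Y = array(Y, d), layer = layer,
       cache = list(xhat = xhat, inv_sd = inv_sd, dims = d, mode = mode))
}

batchnorm_backward <- function(layer, cache, dY) {
  d <- cache$dims
  dYm <- as_channel_matrix(dY)
  dgamma <- colSums(dYm * cache$xhat)
  dbeta <- colSums(dYm)
  if (cache$mode == "train") {
    m <- nrow(dYm)
    t1 <- sweep(dYm, 2, colMeans(dYm))
    t2 <- sweep(cache$xhat, 2, colMeans(dYm * cache$xhat), "*")
    dXm <- sweep(t1 - t2, 2, layer$gamma * cache$inv_sd, "*")
  } else {
    dXm <- sweep(dYm, 2, layer$gamma * cache$inv_sd, "*")
  }
  list(dX = array(dXm, d), grads = list(gamma = dgamma, beta = dbeta))
}

# ---- generic layer dispatch ----

nn_layer_forward <- function(layer, X, mode) {
  switch(layer$type,
    conv1d = c(conv1d_forward(layer, X), list(layer = layer)),
    conv2d = c(conv2d_forward(layer, X), list(layer = layer)),
    maxpool1d = c(maxpool1d_forward(X), list(layer = layer)),
    maxpool2d = c(maxpool2d_forward(X), list(layer = layer)),
    batchnorm = batchnorm_forward(layer, X, mode),
    relu = {
      r <- cpp_relu(X)
      list(Y = r$Y, cache = list(pos = r$pos), layer = layer)
    },
    leaky_relu = list(Y = pmax(X, 0) + layer$alpha * pmin(X, 0),
                      cache = list(pos = X > 0), layer = layer),
    dropout = {
      if (mode %in% c("train", "mc")) {
        dr <- cpp_dropout(X, layer$rate)
        list(Y = dr$Y, cache = list(mask = dr$mask), layer = layer)
      } else {
        list(Y = X, cache = list(mask = NULL), layer = layer)
      }
    },
    gaussian_noise = {
      if (mode == "train") {
        list(Y = X + array(rnorm(length(X), sd = layer$sd), dim(X)),
             cache = NULL, layer = layer)
      } else list(Y = X, cache = NULL, layer = layer)
    },
    flatten = {
      d <- dim(X)
      list(Y = matrix(X, d[1], prod(d[-1])), cache = list(dims = d), layer = layer)
    },
    dense = {
      Y <- X %*% layer$W
      cpp_add_bias(Y, layer$b)
      list(Y = Y, cache = list(X = X), layer = layer)
    },
    bilstm = bilstm_forward(layer, X, mode),
    abort(paste0("Unknown layer type: ", layer$type))
  )
}

nn_layer_backward <- function(layer, cache, dY) {
  switch(layer$type,
    conv1d = conv1d_backward(layer, cache, dY),
    conv2d = conv2d_backward(layer, cache, dY),
    maxpool1d = list(dX = maxpool1d_backward(cache, dY), grads = NULL),
    maxpool2d = list(dX = maxpool2d_backward(cache, dY), grads = NULL),
    batchnorm = batchnorm_backward(layer, cache, dY),
    relu = list(dX = dY * cache$pos, grads = NULL),
    leaky_relu = list(dX = dY * (cache$pos + layer$alpha * !cache$pos), grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dX = dY, grads = NULL)
      else list(dX = dY * cache$mask, grads = NULL)
    },
    gaussian_noise = list(dX = dY, grads = NULL),
    flatten = list(dX = array(dY, cache$dims), grads = NULL),
    dense = list(dX = tcrossprod(dY, layer$W),
                 grads = list(W = crossprod(cache$X, dY), b = colSums(dY))),
    bilstm = bilstm_backward(layer, cache, dY),
    abort(paste0("Unknown layer type: ", layer$type))
  )
}

nn_forward <- function(model, X, mode = "eval") {
  lens <- NULL
  if (is.list(X) && !is.array(X)) { # ragged sequence input
    pb <- pad_ragged(X)
    X <- pb$X
    lens <- pb$lens
  }
  caches <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    layer <- model$layers[[i]]
    if (layer$type == "bilstm") layer$lens <- lens
    step <- nn_layer_forward(layer, X, mode)
    X <- step$Y
    caches[[i]] <- step$cache
    step$layer$lens <- NULL
    model$layers[[i]] <- step$layer
  }
  list(out = X, caches = caches, model = model)
}

nn_softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam / AMSGrad ----

adam_init <- function(layers) {
  lapply(layers, function(l) {
    pn <- intersect(names(l),
                    c("W", "b", "gamma", "beta", "U", "W_r", "U_r", "b_r"))
    if (length(pn) == 0) return(NULL)
    st <- lapply(pn, function(p) list(m = l[[p]] * 0, v = l[[p]] * 0,
                                      vhat = l[[p]] * 0))
    names(st) <- pn
    st
  })
}

# In-place fused update (see src/fastops.cpp). nn_fit deep-copies all
# parameter arrays before training starts and when snapshotting the best
# epoch, so these arrays are never aliased by caller-visible objects.
adam_update <- function(layers, grads_list, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                        amsgrad = FALSE) {
  for (i in seq_along(layers)) {
    g <- grads_list[[i]]
    if (is.null(g)) next
    for (p in names(g)) {
      s <- state[[i]][[p]]
      cpp_adam_step(layers[[i]][[p]], g[[p]], s$m, s$v, s$vhat,
                    lr, beta1, beta2, eps, t, amsgrad)
    }
  }
  list(layers = layers, state = state)
}

param_names <- function(l) {
  intersect(names(l), c("W", "b", "gamma", "beta", "U", "W_r", "U_r", "b_r",
                        "running_mean", "running_var"))
}

copy_params <- function(layers) {
  lapply(layers, function(l) {
    for (p in param_names(l)) l[[p]] <- l[[p]] + 0
    l
  })
}

slice_batch <- function(X, idx) {
  if (is.list(X) && !is.array(X)) return(X[idx]) # ragged input
  d <- dim(X)
  if (length(d) == 3) X[idx, , , drop = FALSE]
  else X[idx, , , , drop = FALSE]
}

nn_loss_grad <- function(logits, y_onehot) {
  p <- nn_softmax(logits)
  n <- nrow(p)
  loss <- -sum(y_onehot * log(p + 1e-12)) / n
  list(loss = loss, dlogits = (p - y_onehot) / n, p = p)
}

nn_evaluate <- function(model, X, y_int, n_classes, batch_size = 256) {
  n <- if (is.list(X) && !is.array(X)) length(X) else dim(X)[1]
  loss <- 0; correct <- 0
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fw <- nn_forward(model, slice_batch(X, idx), mode = "eval")
    Y1 <- diag(n_classes)[y_int[idx], , drop = FALSE]
    lg <- nn_loss_grad(fw$out, Y1)
    loss <- loss + lg$loss * length(idx)
    correct <- correct + sum(max.col(lg$p, ties.method = "first") == y_int[idx])
  }
  c(loss = loss / n, accuracy = correct / n)
}

# Core training loop: minibatch SGD with Adam/AMSGrad, early stopping on
# validation loss, best weights restored.
nn_fit <- function(model, X, y_int, X_val, y_val, n_classes, config) {
  set.seed(config$seed)
  n <- if (is.list(X) && !is.array(X)) length(X) else dim(X)[1]
  model$layers <- copy_params(model$layers) # in-place optimizer: own the arrays
  state <- adam_init(model$layers)
  amsgrad <- identical(config$optimizer, "amsgrad")
  hist <- list()
  best_loss <- Inf; best_layers <- model$layers; wait <- 0; t <- 0
  eye <- diag(n_classes)
  decay <- if (is.null(config$lr_decay)) 1 else config$lr_decay
  for (epoch in seq_len(config$epochs)) {
    lr_epoch <- config$learning_rate * decay^(epoch - 1)
    perm <- sample(n)
    ep_loss <- 0; ep_correct <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- perm[start:min(start + config$batch_size - 1, n)]
      Xb <- slice_batch(X, idx)
      Yb <- eye[y_int[idx], , drop = FALSE]
      fw <- nn_forward(model, Xb, mode = "train")
      model <- fw$model # batch-norm running stats
      lg <- nn_loss_grad(fw$out, Yb)
      ep_loss <- ep_loss + lg$loss * length(idx)
      ep_correct <- ep_correct + sum(max.col(lg$p, ties.method = "first") == y_int[idx])
      dY <- lg$dlogits
      grads_list <- vector("list", length(model$layers))
      for (i in rev(seq_along(model$layers))) {
        bk <- nn_layer_backward(model$layers[[i]], fw$caches[[i]], dY)
        dY <- bk$dX
        grads_list[i] <- list(bk$grads) # keep NULLs as elements
      }
      t <- t + 1
      upd <- adam_update(model$layers, grads_list, state, lr_epoch,
                         t, amsgrad = amsgrad)
      model$layers <- upd$layers
      state <- upd$state
    }
    val <- nn_evaluate(model, X_val, y_val, n_classes)
    hist[[epoch]] <- c(epoch = epoch, loss = ep_loss / n,
                       accuracy = ep_correct / n, val)
    if (isTRUE(config$verbose)) {
      message(sprintf("epoch %d: loss %.4f acc %.3f val_loss %.4f val_acc %.3f",
                      epoch, ep_loss / n, ep_correct / n, val[1], val[2]))
    }
    if (val[["loss"]] < best_loss - 1e-6) {
      best_loss <- val[["loss"]]
      best_layers <- copy_params(model$layers)
      wait <- 0
    } else {
      wait <- wait + 1
      if (wait >= config$patience) break
    }
  }
  model$layers <- best_layers
  hdf <- as.data.frame(do.call(rbind, hist))
  names(hdf) <- c("epoch", "loss", "accuracy", "val_loss", "val_accuracy")
  list(model = model, history = tibble::as_tibble(hdf))
}
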