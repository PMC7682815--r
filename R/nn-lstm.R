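# Bidirectional LSTM layer with masked variable-length batches.
#
# Ragged inputs (a list of L_i x C one-hot matrices) are padded to the batch
# maximum with an explicit length vector; padded timesteps carry the previous
# hidden/cell state forward, so the "final" state of each sample is the state
# after its last real base regardless of padding.

pad_ragged <- function(seqs) {
  lens <- vapply(seqs, nrow, integer(1))
  if (any(lens < 1)) abort("Ragged batch contains an empty sequence")
  Tm <- max(lens)
  C <- ncol(seqs[[1]])
  X <- array(0, c(length(seqs), Tm, C))
  for (i in seq_along(seqs)) X[i, seq_len(lens[i]), ] <- seqs[[i]]
  list(X = X, lens = lens)
}

reverse_time <- function(X, lens) {
  out <- array(0, dim(X))
  for (i in seq_along(lens)) {
    L <- lens[i]
    out[i, seq_len(L), ] <- X[i, L:1, , drop = FALSE]
  }
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

lstm_dir_forward <- function(X, lens, W, U, b) {
  d <- dim(X); n <- d[1]; Tm <- d[2]
  u <- nrow(U)
  G <- array(0, c(n, Tm, 4 * u)) # post-activation gates i,f,g,o
  Cs <- array(0, c(n, Tm, u))
  Hs <- array(0, c(n, Tm, u))
  TC <- array(0, c(n, Tm, u)) # tanh(c_new)
  h <- matrix(0, n, u); cc <- matrix(0, n, u)
  Cin <- d[3]
  for (t in seq_len(Tm)) {
    Z <- matrix(X[, t, ], n, Cin) %*% W + h %*% U
    cpp_add_bias(Z, b)
    i_g <- sigmoid(Z[, 1:u, drop = FALSE])
    f_g <- sigmoid(Z[, (u + 1):(2 * u), drop = FALSE])
    g_g <- tanh(Z[, (2 * u + 1):(3 * u), drop = FALSE])
    o_g <- sigmoid(Z[, (3 * u + 1):(4 * u), drop = FALSE])
    c_new <- f_g * cc + i_g * g_g
    tc <- tanh(c_new)
    h_new <- o_g * tc
    m <- as.numeric(t <= lens)
    h <- h_new * m + h * (1 - m)
    cc <- c_new * m + cc * (1 - m)
    G[, t, ] <- cbind(i_g, f_g, g_g, o_g)
    Cs[, t, ] <- cc
    Hs[, t, ] <- h
    TC[, t, ] <- tc
  }
  list(H = Hs, cache = list(X = X, lens = lens, G = G, Cs = Cs, Hs = Hs,
                            TC = TC, u = u))
}

lstm_dir_backward <- function(cache, W, U, dH) {
  X <- cache$X; lens <- cache$lens; u <- cache$u
  d <- dim(X); n <- d[1]; Tm <- d[2]
  dW <- W * 0; dU <- U * 0; db <- numeric(4 * u)
  dX <- array(0, d)
  dh_next <- matrix(0, n, u)
  dc_next <- matrix(0, n, u)
  for (t in Tm:1) {
    m <- as.numeric(t <= lens)
    i_g <- matrix(cache$G[, t, 1:u], n, u)
    f_g <- matrix(cache$G[, t, (u + 1):(2 * u)], n, u)
    g_g <- matrix(cache$G[, t, (2 * u + 1):(3 * u)], n, u)
    o_g <- matrix(cache$G[, t, (3 * u + 1):(4 * u)], n, u)
    tc <- matrix(cache$TC[, t, ], n, u)
    h_prev <- if (t > 1) matrix(cache$Hs[, t - 1, ], n, u) else matrix(0, n, u)
    c_prev <- if (t > 1) matrix(cache$Cs[, t - 1, ], n, u) else matrix(0, n, u)
    dh <- matrix(dH[, t, ], n, u) + dh_next
    dc_acc <- dc_next
    dh_new <- dh * m
    dh_prev <- dh * (1 - m)
    dc_new <- dc_acc * m + dh_new * o_g * (1 - tc^2)
    dc_prev <- dc_acc * (1 - m) + dc_new * f_g
    do_g <- dh_new * tc
    di_g <- dc_new * g_g
    dg_g <- dc_new * i_g
    df_g <- dc_new * c_prev
    dZ <- cbind(di_g * i_g * (1 - i_g),
                df_g * f_g * (1 - f_g),
                dg_g * (1 - g_g^2),
                do_g * o_g * (1 - o_g))
    dW <- dW + crossprod(matrix(X[, t, ], n, d[3]), dZ)
    dU <- dU + crossprod(h_prev, dZ)
    db <- db + colSums(dZ)
    dX[, t, ] <- tcrossprod(dZ, W)
    dh_next <- dh_prev + tcrossprod(dZ, U)
    dc_next <- dc_prev
  }
  list(dX = dX, dW = dW, dU = dU, db = db)
}

bilstm_init <- function(input_channels, units) {
  u <- units
  mk <- function() {
    b <- numeric(4 * u)
    b[(u + 1):(2 * u)] <- 1 # forget-gate bias
    list(W = he_init(input_channels, c(input_channels, 4 * u)) * 0.5,
         U = array(rnorm(u * 4 * u, sd = 1 / sqrt(u)), c(u, 4 * u)),
         b = b)
  }
  f <- mk(); r <- mk()
  nn_layer("bilstm",
           W = f$W, U = f$U, b = f$b,
           W_r = r$W, U_r = r$U, b_r = r$b,
           units = u, return_sequences = FALSE)
}

bilstm_forward <- function(layer, X, mode) {
  lens <- layer$lens
  if (is.null(lens)) lens <- rep(dim(X)[2], dim(X)[1])
  u <- layer$units
  fwd <- lstm_dir_forward(X, lens, layer$W, layer$U, layer$b)
  Xr <- reverse_time(X, lens)
  rev <- lstm_dir_forward(Xr, lens, layer$W_r, layer$U_r, layer$b_r)
  n <- dim(X)[1]; Tm <- dim(X)[2]
  if (layer$return_sequences) {
    Hr <- reverse_time(rev$H, lens) # back to original time order
    Y <- array(0, c(n, Tm, 2 * u))
    Y[, , 1:u] <- fwd$H
    Y[, , (u + 1):(2 * u)] <- Hr
    for (i in seq_len(n)) { # zero padded positions
      if (lens[i] < Tm) Y[i, (lens[i] + 1):Tm, ] <- 0
    }
  } else {
    Y <- cbind(matrix(fwd$H[, Tm, ], n, u), matrix(rev$H[, Tm, ], n, u))
  }
  list(Y = Y, cache = list(fwd = fwd$cache, rev = rev$cache, lens = lens,
                           Tm = Tm, n = n),
       layer = layer)
}

bilstm_backward <- function(layer, cache, dY) {
  u <- layer$units
  n <- cache$n; Tm <- cache$Tm; lens <- cache$lens
  if (layer$return_sequences) {
    for (i in seq_len(n)) {
      if (lens[i] < Tm) dY[i, (lens[i] + 1):Tm, ] <- 0
    }
    dHf <- dY[, , 1:u, drop = FALSE]
    dHr <- reverse_time(dY[, , (u + 1):(2 * u), drop = FALSE], lens)
  } else {
    dHf <- array(0, c(n, Tm, u))
    dHr <- array(0, c(n, Tm, u))
    dHf[, Tm, ] <- dY[, 1:u, drop = FALSE]
    dHr[, Tm, ] <- dY[, (u + 1):(2 * u), drop = FALSE]
  }
  bf <- lstm_dir_backward(cache$fwd, layer$W, layer$U, dHf)
  br <- lstm_dir_backward(cache$rev, layer$W_r, layer$U_r, dHr)
  dX <- bf$dX + reverse_time(br$dX, lens)
  list(dX = dX,
       grads = list(W = bf$dW, U = bf$dU, b = bf$db,
                    W_r = br$dW, U_r = br$dU, b_r = br$db))
}
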