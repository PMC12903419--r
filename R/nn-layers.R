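# Low-level neural network primitives on BLAS matrix operations.
# Shapes: feature maps are (channels, positions*batch) matrices with the
# position index fastest; 3-D tensors are (channels, positions, batch).

# Broadcast a length-nc vector across nr rows (column-major recycling).
rep_row <- function(v, nr, nc) rep(v, each = nr)

sigmoid <- function(x) 1 / (1 + exp(-x))

# --- dilated 1-D convolution, 'same' zero padding, stride 1 ---------------

conv1d_forward <- function(X, W, b, dilation) {
  d <- dim(X); C <- d[1]; L <- d[2]; B <- d[3]
  K <- ncol(W) / C
  M <- cpp_im2col(X, C, L, B, K, dilation)
  Y <- W %*% M + b
  list(out = Y, cache = list(M = M, C = C, L = L, B = B, K = K,
    dilation = dilation))
}

conv1d_backward <- function(dY, cache, W, need_param_grads = TRUE,
                            need_input_grad = TRUE) {
  C <- cache$C; L <- cache$L; B <- cache$B; K <- cache$K
  d <- cache$dilation
  dW <- db <- NULL
  if (need_param_grads) {
    dW <- tcrossprod(dY, cache$M)
    db <- rowSums(dY)
  }
  if (!need_input_grad) return(list(dX = NULL, dW = dW, db = db))
  dM <- crossprod(W, dY)
  dX <- cpp_col2im(dM, C, L, B, K, d)
  list(dX = dX, dW = dW, db = db)
}

# --- layer normalisation over the channel axis (per position, per example) -

layernorm_forward <- function(Y, g, be, eps = 1e-3) {
  r <- cpp_layernorm_fwd(Y, g, be, eps)
  list(out = r$out, cache = list(Xhat = r$Xhat, inv = r$inv))
}

layernorm_backward <- function(dOut, cache, g, need_param_grads = TRUE) {
  r <- cpp_layernorm_bwd(dOut, cache$Xhat, cache$inv, g, need_param_grads)
  list(dX = r$dX, dg = r$dg, dbe = r$dbe)
}

# --- max pooling (non-overlapping, 'valid') -------------------------------

maxpool_forward <- function(Y, L, B, size) {
  Tn <- L %/% size
  if (Tn < 1) {
    abort(sprintf(
      "pooled length is zero (input %d positions, pool %d); input too short", L, size))
  }
  r <- cpp_maxpool_fwd(Y, L, B, size)
  list(out = r$out, cache = list(amax = r$amax, L = L, B = B, size = size, Tn = Tn))
}

maxpool_backward <- function(dOut, cache) {
  cpp_maxpool_bwd(dOut, cache$amax, cache$L, cache$B, cache$size)
}

# --- gated recurrent layer, reset-after biasing ---------------------------
# Two bias vectors (input and recurrent) per gate set; candidate state uses
# r * (U_h h + b_rh). Returns the final hidden state.

gru_forward <- function(X, p) {
  d <- dim(X); Tn <- d[2]; B <- d[3]
  u <- nrow(p$U) / 3
  h <- matrix(0, u, B)
  steps <- vector("list", Tn)
  iz <- seq_len(u); ir <- u + iz; ih <- 2 * u + iz
  for (t in seq_len(Tn)) {
    x <- X[, t, , drop = FALSE]; dim(x) <- c(d[1], B)
    gx <- p$W %*% x + p$bi
    gh <- p$U %*% h + p$br
    z <- sigmoid(gx[iz, , drop = FALSE] + gh[iz, , drop = FALSE])
    r <- sigmoid(gx[ir, , drop = FALSE] + gh[ir, , drop = FALSE])
    ghh <- gh[ih, , drop = FALSE]
    hh <- tanh(gx[ih, , drop = FALSE] + r * ghh)
    h_new <- z * h + (1 - z) * hh
    steps[[t]] <- list(x = x, h_prev = h, z = z, r = r, hh = hh, ghh = ghh)
    h <- h_new
  }
  list(out = h, cache = list(steps = steps, Tn = Tn, B = B, cin = d[1], u = u))
}

gru_backward <- function(dh, cache, p, need_param_grads = TRUE) {
  u <- cache$u; B <- cache$B; Tn <- cache$Tn; cin <- cache$cin
  dW <- matrix(0, 3 * u, cin); dU <- matrix(0, 3 * u, u)
  dbi <- numeric(3 * u); dbr <- numeric(3 * u)
  dX <- array(0, c(cin, Tn, B))
  for (t in rev(seq_len(Tn))) {
    s <- cache$steps[[t]]
    dz <- dh * (s$h_prev - s$hh)
    dhh <- dh * (1 - s$z)
    dh_direct <- dh * s$z
    da_h <- dhh * (1 - s$hh^2)
    dghh <- da_h * s$r
    dr <- da_h * s$ghh
    da_z <- dz * s$z * (1 - s$z)
    da_r <- dr * s$r * (1 - s$r)
    dgx <- rbind(da_z, da_r, da_h)
    dgh <- rbind(da_z, da_r, dghh)
    if (need_param_grads) {
      dW <- dW + tcrossprod(dgx, s$x)
      dU <- dU + tcrossprod(dgh, s$h_prev)
      dbi <- dbi + rowSums(dgx)
      dbr <- dbr + rowSums(dgh)
    }
    dX[, t, ] <- crossprod(p$W, dgx)
    dh <- dh_direct + crossprod(p$U, dgh)
  }
  list(dX = dX, dW = dW, dU = dU, dbi = dbi, dbr = dbr)
}

# --- dense ----------------------------------------------------------------

dense_forward <- function(X, W, b) list(out = W %*% X + b, cache = X)

dense_backward <- function(dY, X, W, need_param_grads = TRUE) {
  list(
    dX = crossprod(W, dY),
    dW = if (need_param_grads) tcrossprod(dY, X) else NULL,
    db = if (need_param_grads) rowSums(dY) else NULL
  )
}

softmax_cols <- function(Z) {
  Z <- Z - rep_row(apply(Z, 2, max), nrow(Z), ncol(Z))
  E <- exp(Z)
  E / rep_row(colSums(E), nrow(Z), ncol(Z))
}
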