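#' Architecture configuration of the convolutional-recurrent classifier
#'
#' The fixed optimised architecture: four 1-D convolutional blocks with 108,
#' 144, 192 and 256 filters, kernel size 9 and dilations 1, 4, 16 and 64;
#' each block is conv -> layer normalisation -> ReLU -> dropout (0.34) ->
#' max-pool (4). A bidirectional gated recurrent layer with 128 units per
#' direction (reset-after biasing, i.e. separate input and recurrent bias
#' vectors) follows, then layer normalisation and dropout, two dense layers
#' of 64 and 32 units (each with layer normalisation and dropout) and a
#' 2-unit softmax output. Convolutional, recurrent and dense kernels carry
#' L1-L2 regularisation (lambda = 1.2e-5).
#'
#' @param conv_filters Integer vector of per-block filter counts.
#' @param kernel_size Convolution kernel size.
#' @param dilations Integer vector of per-block dilation rates.
#' @param pool_size Max-pooling window per block.
#' @param dropout Dropout rate.
#' @param gru_units Units per recurrent direction.
#' @param dense_units Integer vector of dense layer widths.
#' @param output_units Output classes (softmax).
#' @param l1l2_lambda L1 and L2 regularisation weight on kernels.
#' @return A list of class `smoops_arch`.
#' @export
arch_config <- function(conv_filters = c(108L, 144L, 192L, 256L),
                        kernel_size = 9L,
                        dilations = c(1L, 4L, 16L, 64L),
                        pool_size = 4L,
                        dropout = 0.34,
                        gru_units = 128L,
                        dense_units = c(64L, 32L),
                        output_units = 2L,
                        l1l2_lambda = 1.2e-5) {
  if (length(conv_filters) != length(dilations)) {
    abort("`conv_filters` and `dilations` must have equal length")
  }
  if (any(c(conv_filters, kernel_size, pool_size, gru_units, dense_units,
    output_units) < 1)) {
    abort("architecture sizes must be positive")
  }
  structure(
    list(conv_filters = conv_filters, kernel_size = kernel_size,
      dilations = dilations, pool_size = pool_size, dropout = dropout,
      gru_units = gru_units, dense_units = dense_units,
      output_units = output_units, l1l2_lambda = l1l2_lambda),
    class = "smoops_arch"
  )
}

glorot_uniform <- function(nr, nc, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(runif(nr * nc, -lim, lim), nr, nc)
}

orthogonal_init <- function(nr, nc) {
  a <- matrix(rnorm(max(nr, nc)^2), max(nr, nc))
  q <- qr.Q(qr(a))
  q[seq_len(nr), seq_len(nc), drop = FALSE]
}

#' Build the classifier for a given input channel count
#'
#' Instantiates seeded initial weights (Glorot uniform kernels, orthogonal
#' recurrent matrices, zero biases, unit layer-norm scales) for the
#' architecture in [arch_config()].
#'
#' @param n_channels Number of input channels (>= 1).
#' @param arch An [arch_config()].
#' @param seed Integer seed for the initialisation.
#' @return An object of class `smoops_model`.
#' @export
#' @examples
#' m <- build_model(4)
#' count_parameters(m)
build_model <- function(n_channels, arch = arch_config(), seed = 1L) {
  if (n_channels < 1) abort("`n_channels` must be >= 1")
  K <- arch$kernel_size
  with_seed(seed, {
    params <- list()
    cin <- n_channels
    params$conv <- purrr::map(seq_along(arch$conv_filters), function(i) {
      f <- arch$conv_filters[i]
      W <- glorot_uniform(f, K * cin, fan_in = K * cin, fan_out = K * f)
      out <- list(W = W, b = numeric(f), g = rep(1, f), be = numeric(f))
      cin <<- f
      out
    })
    u <- arch$gru_units
    make_dir <- function() {
      list(
        W = glorot_uniform(3 * u, cin, fan_in = cin, fan_out = 3 * u),
        U = do.call(rbind, purrr::map(1:3, ~ orthogonal_init(u, u))),
        bi = numeric(3 * u), br = numeric(3 * u)
      )
    }
    params$gru <- list(fwd = make_dir(), bwd = make_dir())
    width <- 2 * u
    params$gru_ln <- list(g = rep(1, width), be = numeric(width))
    params$dense <- purrr::map(arch$dense_units, function(du) {
      out <- list(
        W = glorot_uniform(du, width, fan_in = width, fan_out = du),
        b = numeric(du), g = rep(1, du), be = numeric(du)
      )
      width <<- du
      out
    })
    params$out <- list(
      W = glorot_uniform(arch$output_units, width, fan_in = width,
        fan_out = arch$output_units),
      b = numeric(arch$output_units)
    )
    structure(
      list(params = params, arch = arch, n_channels = n_channels, seed = seed),
      class = "smoops_model"
    )
  })
}

#' Count trainable parameters of a model
#'
#' Sums all trainable weights: convolution kernels and biases, layer
#' normalisation scale/offset pairs, both recurrent bias sets, dense kernels
#' and biases.
#'
#' @param model A `smoops_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  total <- 0
  walk <- function(x) {
    if (is.numeric(x)) {
      total <<- total + length(x)
    } else if (is.list(x)) {
      for (el in x) walk(el)
    }
  }
  walk(model$params)
  as.integer(total)
}

#' @export
print.smoops_model <- function(x, ...) {
  cat(sprintf(
    "Convolutional-recurrent classifier: %d input channel(s), %s trainable parameters\n",
    x$n_channels, format(count_parameters(x), big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs; best validation AUROC %.3f\n",
      nrow(x$history), max(x$history$val_auroc)))
  }
  invisible(x)
}

# Full forward pass. X: (channels, positions, batch). `dropout` NULL for
# inference or a dropout rate for training (masks drawn from the ambient
# RNG). Returns softmax probabilities and, if keep_cache, all layer caches.
model_forward <- function(model, X, dropout = NULL, keep_cache = FALSE) {
  p <- model$params; arch <- model$arch
  d <- dim(X); L <- d[2]; B <- d[3]
  caches <- list(conv = list(), L = L, B = B)
  cur <- X
  dim(cur) <- c(d[1], L * B)
  curL <- L
  drop_mask <- function(mat) {
    if (is.null(dropout) || dropout <= 0) return(NULL)
    (runif(length(mat)) >= dropout) / (1 - dropout)
  }
  for (i in seq_along(p$conv)) {
    pc <- p$conv[[i]]
    dim(cur) <- c(nrow(cur), curL, B)
    cv <- conv1d_forward(cur, pc$W, pc$b, arch$dilations[i])
    ln <- layernorm_forward(cv$out, pc$g, pc$be)
    rl <- cpp_relu(ln$out)
    act <- rl$out
    relu_mask <- rl$mask
    dm <- drop_mask(act)
    if (!is.null(dm)) act <- act * dm
    mp <- maxpool_forward(act, curL, B, arch$pool_size)
    caches$conv[[i]] <- list(conv = cv$cache, ln = ln$cache,
      relu = relu_mask, drop = dm, pool = mp$cache)
    cur <- mp$out
    curL <- mp$cache$Tn
  }
  dim(cur) <- c(nrow(cur), curL, B)
  gf <- gru_forward(cur, p$gru$fwd)
  gb <- gru_forward(cur[, rev(seq_len(curL)), , drop = FALSE], p$gru$bwd)
  h <- rbind(gf$out, gb$out)
  ln_g <- layernorm_forward(h, p$gru_ln$g, p$gru_ln$be)
  cur2 <- ln_g$out
  dm_g <- drop_mask(cur2)
  if (!is.null(dm_g)) cur2 <- cur2 * dm_g
  dcaches <- list()
  for (j in seq_along(p$dense)) {
    pd <- p$dense[[j]]
    dn <- dense_forward(cur2, pd$W, pd$b)
    ln <- layernorm_forward(dn$out, pd$g, pd$be)
    out <- ln$out
    dm <- drop_mask(out)
    if (!is.null(dm)) out <- out * dm
    dcaches[[j]] <- list(x = dn$cache, ln = ln$cache, drop = dm)
    cur2 <- out
  }
  logits <- p$out$W %*% cur2 + p$out$b
  probs <- softmax_cols(logits)
  if (keep_cache) {
    caches$gru_in_L <- curL
    caches$gf <- gf$cache; caches$gb <- gb$cache
    caches$gru_ln <- ln_g$cache; caches$gru_drop <- dm_g
    caches$gru_h <- h
    caches$dense <- dcaches
    caches$out_x <- cur2
    caches$probs <- probs
  }
  list(probs = probs, caches = if (keep_cache) caches else NULL)
}

# Backward pass from d(logits). Returns parameter gradients (same structure
# as params) and optionally the gradient with respect to the input tensor.
model_backward <- function(model, caches, dlogits, need_param_grads = TRUE,
                           need_input_grad = FALSE) {
  p <- model$params; arch <- model$arch
  g <- list()
  g$out <- list(
    W = if (need_param_grads) tcrossprod(dlogits, caches$out_x) else NULL,
    b = if (need_param_grads) rowSums(dlogits) else NULL
  )
  dcur <- crossprod(p$out$W, dlogits)
  g$dense <- vector("list", length(p$dense))
  for (j in rev(seq_along(p$dense))) {
    dc <- caches$dense[[j]]
    if (!is.null(dc$drop)) dcur <- dcur * dc$drop
    lb <- layernorm_backward(dcur, dc$ln, p$dense[[j]]$g, need_param_grads)
    db <- dense_backward(lb$dX, dc$x, p$dense[[j]]$W, need_param_grads)
    g$dense[[j]] <- list(W = db$dW, b = db$db, g = lb$dg, be = lb$dbe)
    dcur <- db$dX
  }
  if (!is.null(caches$gru_drop)) dcur <- dcur * caches$gru_drop
  lb <- layernorm_backward(dcur, caches$gru_ln, p$gru_ln$g, need_param_grads)
  g$gru_ln <- list(g = lb$dg, be = lb$dbe)
  u <- nrow(p$gru$fwd$U) / 3
  dh <- lb$dX
  gfb <- gru_backward(dh[seq_len(u), , drop = FALSE], caches$gf, p$gru$fwd,
    need_param_grads)
  gbb <- gru_backward(dh[u + seq_len(u), , drop = FALSE], caches$gb, p$gru$bwd,
    need_param_grads)
  g$gru <- list(
    fwd = list(W = gfb$dW, U = gfb$dU, bi = gfb$dbi, br = gfb$dbr),
    bwd = list(W = gbb$dW, U = gbb$dU, bi = gbb$dbi, br = gbb$dbr)
  )
  Tn <- caches$gru_in_L
  dgru_in <- gfb$dX + gbb$dX[, rev(seq_len(Tn)), , drop = FALSE]
  dcur <- dgru_in
  dim(dcur) <- c(dim(dgru_in)[1], Tn * caches$B)
  g$conv <- vector("list", length(p$conv))
  for (i in rev(seq_along(p$conv))) {
    cc <- caches$conv[[i]]
    dcur <- maxpool_backward(dcur, cc$pool)
    if (!is.null(cc$drop)) dcur <- dcur * cc$drop
    dcur[!cc$relu] <- 0
    lb <- layernorm_backward(dcur, cc$ln, p$conv[[i]]$g, need_param_grads)
    cb <- conv1d_backward(lb$dX, cc$conv, p$conv[[i]]$W, need_param_grads,
      need_input_grad = i > 1 || need_input_grad)
    g$conv[[i]] <- list(W = cb$dW, b = cb$db, g = lb$dg, be = lb$dbe)
    if (!is.null(cb$dX)) {
      dcur <- cb$dX
      dim(dcur) <- c(dim(cb$dX)[1], dim(cb$dX)[2] * dim(cb$dX)[3])
    }
  }
  list(grads = g, dX = if (need_input_grad) {
    dX <- dcur
    dim(dX) <- c(model$n_channels, caches$L, caches$B)
    dX
  } else {
    NULL
  })
}
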