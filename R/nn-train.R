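#' Training configuration
#'
#' Adam with learning rate 1e-4 and categorical cross-entropy, early stopping
#' on validation AUROC with 20-epoch patience and best-weights restore.
#' `max_epochs` caps the otherwise unlimited training for desk-scale runs;
#' batch size defaults to 32 and may be set anywhere in 8-64.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Epoch cap.
#' @param patience Early-stopping patience (epochs without validation AUROC
#'   improvement).
#' @param seed Integer seed controlling shuffling, dropout and weight
#'   initialisation offsets.
#' @param verbose Print per-epoch progress.
#' @return A list of class `smoops_train_config`.
#' @export
training_config <- function(learning_rate = 1e-4, batch_size = 32L,
                            max_epochs = 100L, patience = 20L, seed = 1L,
                            verbose = FALSE) {
  if (learning_rate <= 0) abort("`learning_rate` must be positive")
  if (patience < 1) abort("`patience` must be >= 1")
  structure(
    list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), patience = as.integer(patience),
      seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "smoops_train_config"
  )
}

# Flat-vector helpers over the nested parameter list ------------------------
# The parameter tree is flattened to one numeric vector for the optimizer;
# unlist/relist keep a stable leaf order once gradient trees are reordered
# to the parameter tree's top-level names.

# 1 where a flat element belongs to a kernel matrix (W or U), else 0.
kernel_mask <- function(params) {
  rec <- function(p, nm) {
    if (is.numeric(p)) {
      return(rep(if (!is.null(nm) && nm %in% c("W", "U")) 1 else 0, length(p)))
    }
    keys <- if (!is.null(names(p))) names(p) else rep(list(NULL), length(p))
    unlist(lapply(seq_along(p), function(i) {
      rec(p[[i]], if (is.character(keys)) keys[[i]] else NULL)
    }), use.names = FALSE)
  }
  rec(params, NULL)
}

# Collect numeric leaves (in template order) into one vector, and restore.
collect_leaves <- function(tree, template, acc) {
  keys <- if (!is.null(names(template))) names(template) else seq_along(template)
  for (k in keys) {
    if (is.numeric(template[[k]])) {
      acc[[length(acc) + 1L]] <- tree[[k]]
    } else {
      acc <- collect_leaves(tree[[k]], template[[k]], acc)
    }
  }
  acc
}

flatten_params <- function(tree, template = tree) {
  unlist(collect_leaves(tree, template, list()), use.names = FALSE)
}

unflatten_params <- function(flat, skeleton) {
  pos <- 0L
  rec <- function(sk) {
    if (is.numeric(sk)) {
      n <- length(sk)
      out <- flat[(pos + 1L):(pos + n)]
      pos <<- pos + n
      dim(out) <- dim(sk)
      return(out)
    }
    for (i in seq_along(sk)) sk[[i]] <- rec(sk[[i]])
    sk
  }
  rec(skeleton)
}

adam_step_flat <- function(state, grad, lr, t,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad * grad
  state$flat <- state$flat -
    lr * (state$m / (1 - beta1^t)) / (sqrt(state$v / (1 - beta2^t)) + eps)
  state
}

one_hot_labels <- function(label, idx) {
  y <- matrix(0, 2, length(idx))
  y[1, label[idx] == "negative"] <- 1
  y[2, label[idx] == "positive"] <- 1
  y
}

#' Predict class probabilities for encoded examples
#'
#' @param model A trained (or freshly built) `smoops_model`.
#' @param encoded A `smoops_encoded` object with a channel set matching the
#'   model.
#' @param indices Example indices (default all).
#' @param batch_size Prediction batch size.
#' @return Numeric vector of positive-class probabilities.
#' @export
predict_proba <- function(model, encoded, indices = NULL, batch_size = 64L) {
  if (is.null(indices)) indices <- seq_len(dim(encoded$x)[3])
  if (dim(encoded$x)[1] != model$n_channels) {
    abort(sprintf("encoded data has %d channels; model expects %d",
      dim(encoded$x)[1], model$n_channels))
  }
  out <- numeric(length(indices))
  for (start in seq(1, length(indices), by = batch_size)) {
    sel <- indices[start:min(start + batch_size - 1L, length(indices))]
    X <- encoded$x[, , sel, drop = FALSE]
    out[start:(start + length(sel) - 1L)] <- model_forward(model, X)$probs[2, ]
  }
  out
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed from the rank statistic of the
#' positive-class scores; tied scores contribute half credit.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Logical or factor; `TRUE`/"positive" marks the positive
#'   class.
#' @return AUROC in `[0, 1]`.
#' @export
auroc_score <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "positive"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) abort("AUROC undefined for a single-class set")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train the classifier
#'
#' Minibatch Adam on categorical cross-entropy with the L1-L2 kernel penalty,
#' early stopping on (balanced) validation AUROC with best-weights restore.
#' Fully deterministic given the config seed.
#'
#' @param model A `smoops_model` from [build_model()].
#' @param encoded A `smoops_encoded` object.
#' @param split A `smoops_split` from [split_and_balance()].
#' @param cfg A [training_config()].
#' @return The model with updated weights plus `history` (per-epoch tibble of
#'   `loss` and `val_auroc`) and `best_epoch`.
#' @export
train_model <- function(model, encoded, split, cfg = training_config()) {
  lambda <- model$arch$l1l2_lambda
  drop_rate <- model$arch$dropout
  train_idx <- split$train_bal
  val_idx <- split$validation_bal
  skeleton <- model$params
  flat0 <- flatten_params(skeleton)
  kmask <- kernel_mask(skeleton)
  with_seed(cfg$seed, {
    state <- list(m = numeric(length(flat0)), v = numeric(length(flat0)),
      flat = flat0)
    best_flat <- flat0
    best_auroc <- -Inf
    best_epoch <- 0L
    wait <- 0L
    history <- list()
    t_global <- 0L
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample(train_idx)
      losses <- numeric(0)
      for (start in seq(1, length(ord), by = cfg$batch_size)) {
        sel <- ord[start:min(start + cfg$batch_size - 1L, length(ord))]
        X <- encoded$x[, , sel, drop = FALSE]
        Y <- one_hot_labels(encoded$label, sel)
        fw <- model_forward(model, X, dropout = drop_rate, keep_cache = TRUE)
        eps <- 1e-12
        loss <- -mean(colSums(Y * log(fw$probs + eps))) +
          lambda * sum(kmask * (abs(state$flat) + state$flat^2))
        if (!is.finite(loss)) {
          abort(sprintf("non-finite loss at epoch %d (batch starting %d)",
            epoch, start))
        }
        losses <- c(losses, loss)
        dlogits <- (fw$probs - Y) / length(sel)
        bw <- model_backward(model, fw$caches, dlogits)
        gflat <- flatten_params(bw$grads, skeleton)
        gflat <- gflat + lambda * kmask * (sign(state$flat) + 2 * state$flat)
        t_global <- t_global + 1L
        state <- adam_step_flat(state, gflat, cfg$learning_rate, t_global)
        model$params <- unflatten_params(state$flat, skeleton)
      }
      val_scores <- predict_proba(model, encoded, val_idx)
      val_auroc <- auroc_score(val_scores, encoded$label[val_idx])
      history[[epoch]] <- tibble(epoch = epoch, loss = mean(losses),
        val_auroc = val_auroc)
      if (cfg$verbose) {
        message(sprintf("epoch %3d  loss %.4f  val AUROC %.4f",
          epoch, mean(losses), val_auroc))
      }
      if (val_auroc > best_auroc) {
        best_auroc <- val_auroc
        best_flat <- state$flat
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    model$params <- unflatten_params(best_flat, skeleton)
    model$history <- dplyr::bind_rows(history)
    model$best_epoch <- best_epoch
    model$val_auroc <- best_auroc
    model
  })
}

#' Evaluate a model on labelled examples
#'
#' AUROC by rank statistic over the positive-class probability, accuracy at
#' the argmax.
#'
#' @param model A `smoops_model`.
#' @param encoded A `smoops_encoded` object.
#' @param indices Example indices (default all; for the evaluation protocol
#'   pass the combined validation and test indices).
#' @return A one-row tibble `auroc`, `accuracy`, `n`.
#' @export
evaluate_model <- function(model, encoded, indices = NULL) {
  if (is.null(indices)) indices <- seq_len(dim(encoded$x)[3])
  scores <- predict_proba(model, encoded, indices)
  labs <- encoded$label[indices]
  tibble(
    auroc = auroc_score(scores, labs),
    accuracy = mean((scores > 0.5) == (labs == "positive")),
    n = length(indices)
  )
}
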