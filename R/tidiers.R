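# broom-style tidiers for the fitted objects.

#' Tidy a permutation-test result
#'
#' One row per connectivity metric with the observed value and permutation p.
#'
#' @param x A `smoops_permtest`.
#' @param ... Unused.
#' @return A tibble `metric`, `observed`, `null_mean`, `null_sd`, `p_value`.
#' @export
tidy.smoops_permtest <- function(x, ...) {
  purrr::map_dfr(names(x$p_values), function(m) {
    tibble(
      metric = m,
      observed = x$observed[[m]],
      null_mean = mean(x$null_samples[[m]], na.rm = TRUE),
      null_sd = sd(x$null_samples[[m]], na.rm = TRUE),
      p_value = unname(x$p_values[m])
    )
  })
}

#' Glance at a permutation-test result
#'
#' @param x A `smoops_permtest`.
#' @param ... Unused.
#' @return A one-row tibble `n_iter`, `degree_tolerance`, `focal_size`,
#'   `min_p`.
#' @export
glance.smoops_permtest <- function(x, ...) {
  tibble(
    n_iter = x$n_iter, degree_tolerance = x$degree_tolerance,
    focal_size = x$focal_size, min_p = min(x$p_values)
  )
}

#' Tidy a trained classifier: the per-epoch training history
#'
#' @param x A trained `smoops_model`.
#' @param ... Unused.
#' @return A tibble `epoch`, `loss`, `val_auroc`.
#' @export
tidy.smoops_model <- function(x, ...) {
  if (is.null(x$history)) {
    return(tibble(epoch = integer(), loss = double(), val_auroc = double()))
  }
  x$history
}

#' Glance at a trained classifier
#'
#' @param x A `smoops_model`.
#' @param ... Unused.
#' @return A one-row tibble `n_channels`, `n_parameters`, `epochs_trained`,
#'   `best_epoch`, `val_auroc`.
#' @export
glance.smoops_model <- function(x, ...) {
  tibble(
    n_channels = x$n_channels,
    n_parameters = count_parameters(x),
    epochs_trained = if (is.null(x$history)) 0L else nrow(x$history),
    best_epoch = x$best_epoch %||% NA_integer_,
    val_auroc = x$val_auroc %||% NA_real_
  )
}

#' Tidy a profile clustering
#'
#' @param x A `smoops_clusters`.
#' @param ... Unused.
#' @return The assignment tibble with the 2-D embedding columns `dim1`,
#'   `dim2`.
#' @export
tidy.smoops_clusters <- function(x, ...) {
  dplyr::mutate(x$assignment,
    dim1 = x$embedding[match(.data$gene_id, rownames(x$embedding)), 1],
    dim2 = x$embedding[match(.data$gene_id, rownames(x$embedding)), 2]
  )
}

#' Glance at a profile clustering
#'
#' @param x A `smoops_clusters`.
#' @param ... Unused.
#' @return A one-row tibble `k` and per-cluster sizes `n_1`, `n_2`, ...
#' @export
glance.smoops_clusters <- function(x, ...) {
  sizes <- table(x$assignment$cluster)
  out <- tibble(k = x$k)
  for (nm in names(sizes)) out[[paste0("n_", nm)]] <- as.integer(sizes[[nm]])
  out
}
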