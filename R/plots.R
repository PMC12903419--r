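# ggplot2 diagnostics for the main result types.

#' Plot a permutation null distribution against the observed value
#'
#' Histogram of the null samples per metric with the observed value as a
#' dashed line, annotated with the permutation p.
#'
#' @param object A `smoops_permtest`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smoops_permtest <- function(object, ...) {
  nulls <- tidyr::pivot_longer(object$null_samples,
    dplyr::everything(), names_to = "metric", values_to = "value")
  obs <- tidy(object)
  ggplot2::ggplot(nulls, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(data = obs,
      ggplot2::aes(xintercept = .data$observed),
      linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_text(data = obs, ggplot2::aes(
      x = .data$observed, y = Inf,
      label = sprintf("p = %.3g", .data$p_value)),
      vjust = 1.5, hjust = -0.05, size = 3) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::labs(x = "metric value", y = "null count",
      title = sprintf("Degree-matched permutation test (%d iterations)",
        object$n_iter))
}

#' Plot a classifier training history
#'
#' @param object A trained `smoops_model`.
#' @param ... Unused.
#' @return A ggplot of loss and validation AUROC per epoch.
#' @export
autoplot.smoops_model <- function(object, ...) {
  h <- tidy(object)
  long <- tidyr::pivot_longer(h, c("loss", "val_auroc"),
    names_to = "quantity", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(title = "Training history", x = "epoch", y = NULL)
}

#' Plot the 2-D embedding of clustered importance profiles
#'
#' @param object A `smoops_clusters`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.smoops_clusters <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
    colour = factor(.data$cluster))) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(colour = "cluster", x = "PCo 1", y = "PCo 2",
      title = "Binned importance profiles")
}

#' Plot per-dataset AUROC improvements
#'
#' Dot-and-error plot of the paired AUROC deltas contributed by each
#' dataset, annotated with the one-sample t-test p value.
#'
#' @param improvements Tibble from [dataset_improvement()] rows (with
#'   `deltas` list-column).
#' @return A ggplot.
#' @export
plot_improvement <- function(improvements) {
  pts <- improvements |>
    dplyr::select("dataset", "deltas") |>
    tidyr::unnest("deltas")
  ggplot2::ggplot(pts, ggplot2::aes(.data$dataset, .data$deltas)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar", width = 0.3,
      colour = "firebrick") +
    ggplot2::geom_text(data = improvements, ggplot2::aes(
      y = Inf, label = sprintf("p = %.3g", .data$p_value)),
      vjust = 1.5, size = 3) +
    ggplot2::labs(x = NULL, y = "AUROC improvement",
      title = "Per-dataset contribution across the powerset")
}

#' Heatmap of per-bin nucleotide composition differences
#'
#' @param diff Tibble from [binned_nucleotide_diff()].
#' @return A ggplot.
#' @export
plot_composition_diff <- function(diff) {
  df <- dplyr::mutate(diff,
    bin_index = as.integer(factor(.data$bin, levels = unique(.data$bin))),
    nucleotide = gsub("T", "U", .data$nucleotide))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_index, .data$nucleotide,
    fill = .data$diff)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
      high = "firebrick") +
    ggplot2::labs(x = "bin (5' to 3')", y = NULL, fill = "group - control",
      title = "Per-bin nucleotide composition difference")
}

#' Plot binned signal medians with bootstrap ribbons
#'
#' @param med Tibble from [binned_signal_median()].
#' @return A ggplot.
#' @export
plot_signal_median <- function(med) {
  df <- dplyr::mutate(med,
    bin_index = as.integer(factor(.data$bin, levels = unique(.data$bin))))
  ggplot2::ggplot(df, ggplot2::aes(.data$bin_index, .data$median,
    colour = .data$set, fill = .data$set)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lo, ymax = .data$ci_hi),
      alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "bin (5' to 3')", y = "median normalised signal",
      title = "Binned signal medians (95% bootstrap CI)")
}
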