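#' Enumerate all non-empty dataset subsets
#'
#' Deterministic canonical order: by subset size, then lexicographically by
#' the positions of the members in the input dataset list. With 7 datasets
#' this yields the 127 subsets of the full powerset analysis.
#'
#' @param datasets Character vector of dataset names (>= 1, unique).
#' @return A list of character vectors.
#' @export
#' @examples
#' length(enumerate_subsets(letters[1:7])) # 127
enumerate_subsets <- function(datasets) {
  if (length(datasets) < 1) abort("need at least one dataset")
  if (anyDuplicated(datasets)) abort("dataset names must be unique")
  unlist(
    lapply(seq_along(datasets), function(k) combn(datasets, k, simplify = FALSE)),
    recursive = FALSE
  )
}

subset_key <- function(subset, datasets) {
  paste(datasets[datasets %in% subset], collapse = "+")
}

#' Train one model per dataset subset, in replicates
#'
#' For every non-empty subset of `datasets`, trains `replicates` models (the
#' subset's channels are selected from the full encoded tensor) and evaluates
#' each on the combined balanced validation and test examples. Replicate
#' seeds are `cfg$seed + 1000 * subset_index + replicate`.
#'
#' @param encoded A `smoops_encoded` object holding all requested datasets.
#' @param split A `smoops_split`.
#' @param datasets Dataset names to take the powerset of.
#' @param replicates Models per subset (default 8).
#' @param cfg A [training_config()] used for every run.
#' @param arch An [arch_config()] (the fixed optimised architecture by
#'   default).
#' @param rbp_panel Panel RBP names (when `postar3` is among the datasets).
#' @return A tibble of class `smoops_powerset`: `subset` (canonical key),
#'   `n_datasets`, `replicate`, `auroc`, `accuracy`, `best_epoch`.
#' @export
run_powerset <- function(encoded, split, datasets = encoded$datasets,
                         replicates = 8L, cfg = training_config(),
                         arch = arch_config(), rbp_panel = character()) {
  subsets <- enumerate_subsets(datasets)
  eval_idx <- c(split$validation_bal, split$test_bal)
  rows <- vector("list", length(subsets) * replicates)
  k <- 0L
  for (si in seq_along(subsets)) {
    ss <- subsets[[si]]
    e <- if (setequal(ss, encoded$datasets)) {
      encoded
    } else {
      subset_channels(encoded, ss, rbp_panel = rbp_panel)
    }
    for (r in seq_len(replicates)) {
      seed_r <- cfg$seed + 1000L * si + r
      model <- build_model(dim(e$x)[1], arch = arch, seed = seed_r)
      run_cfg <- cfg
      run_cfg$seed <- seed_r
      model <- tryCatch(
        train_model(model, e, split, run_cfg),
        error = function(err) {
          abort(sprintf("training failed for subset {%s} replicate %d: %s",
            subset_key(ss, datasets), r, conditionMessage(err)))
        }
      )
      ev <- evaluate_model(model, e, eval_idx)
      k <- k + 1L
      rows[[k]] <- tibble(
        subset = subset_key(ss, datasets), n_datasets = length(ss),
        replicate = r, auroc = ev$auroc, accuracy = ev$accuracy,
        best_epoch = model$best_epoch
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("smoops_powerset", class(out))
  attr(out, "datasets") <- datasets
  out
}

#' Best replicate per subset
#'
#' Maximum AUROC per subset; ties broken by the lowest replicate index.
#'
#' @param runs A run tibble from [run_powerset()] (columns `subset`,
#'   `replicate`, `auroc`, ...).
#' @return One row per subset.
#' @export
best_per_subset <- function(runs) {
  runs |>
    dplyr::group_by(.data$subset) |>
    dplyr::arrange(dplyr::desc(.data$auroc), .data$replicate, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

# Named AUROC lookup from a best-per-subset table.
auroc_lookup <- function(best) setNames(best$auroc, best$subset)

# One-sample t-test tolerant of (numerically) constant deltas.
delta_t_test <- function(deltas) {
  out <- tryCatch(t.test(deltas), error = function(e) NULL)
  if (!is.null(out) && is.finite(out$statistic)) return(out)
  m <- mean(deltas)
  if (abs(m) < 1e-12) {
    list(statistic = c(t = 0), p.value = 1)
  } else {
    list(statistic = c(t = Inf * sign(m)), p.value = 0)
  }
}

#' AUROC improvement contributed by one dataset
#'
#' For every non-empty base subset S not containing dataset `d`, the paired
#' delta `AUROC(S + d) - AUROC(S)` over best-per-subset models, with a
#' two-sided one-sample t-test of the mean delta against zero.
#'
#' @param best Best-per-subset tibble (from [best_per_subset()]) covering all
#'   non-empty subsets of `datasets`.
#' @param dataset The dataset whose contribution is measured.
#' @param datasets The full dataset list (defaults to the powerset
#'   attribute).
#' @return A one-row tibble `dataset`, `n_pairs`, `mean_delta`, `statistic`,
#'   `p_value`, plus the deltas in the `deltas` list-column.
#' @export
dataset_improvement <- function(best, dataset, datasets = attr(best, "datasets")) {
  datasets <- datasets %||% attr(best, "datasets")
  if (is.null(datasets)) abort("supply `datasets`")
  if (length(datasets) < 2) abort("need at least two datasets for paired deltas")
  if (!dataset %in% datasets) abort(sprintf("unknown dataset '%s'", dataset))
  A <- auroc_lookup(best)
  others <- setdiff(datasets, dataset)
  bases <- enumerate_subsets(others)
  deltas <- vapply(bases, function(S) {
    A[[subset_key(c(S, dataset), datasets)]] - A[[subset_key(S, datasets)]]
  }, numeric(1))
  tt <- delta_t_test(deltas)
  tibble(
    dataset = dataset, n_pairs = length(deltas), mean_delta = mean(deltas),
    statistic = unname(tt$statistic), p_value = tt$p.value,
    deltas = list(deltas)
  )
}

#' Pairwise informational overlap between two datasets
#'
#' For every subset T of the remaining datasets (including the empty set):
#' `AUROC(T + d1 + d2) - max(AUROC(T + d1), AUROC(T + d2))`. Negative means
#' the pair is redundant (adding both is no better than the better single
#' addition); a two-sided one-sample t-test compares the mean to zero.
#'
#' @inheritParams dataset_improvement
#' @param d1,d2 The dataset pair (distinct).
#' @return A one-row tibble as in [dataset_improvement()].
#' @export
pairwise_overlap <- function(best, d1, d2, datasets = attr(best, "datasets")) {
  if (is.null(datasets)) abort("supply `datasets`")
  if (identical(d1, d2)) abort("`d1` and `d2` must differ")
  if (!all(c(d1, d2) %in% datasets)) abort("unknown dataset in pair")
  A <- auroc_lookup(best)
  rest <- setdiff(datasets, c(d1, d2))
  bases <- c(list(character()), if (length(rest)) enumerate_subsets(rest))
  deltas <- vapply(bases, function(S) {
    A[[subset_key(c(S, d1, d2), datasets)]] -
      max(A[[subset_key(c(S, d1), datasets)]], A[[subset_key(c(S, d2), datasets)]])
  }, numeric(1))
  tt <- delta_t_test(deltas)
  tibble(
    dataset = paste(d1, d2, sep = ":"), n_pairs = length(deltas),
    mean_delta = mean(deltas), statistic = unname(tt$statistic),
    p_value = tt$p.value, deltas = list(deltas)
  )
}
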