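#' Calling thresholds for smOOPs and common control genes
#'
#' Strict inequalities exactly as used throughout: smOOPs require
#' `padj < padj_max` and `lfc > lfc_min` in both assays; common controls
#' require `padj > control_padj_min` and `|lfc| < control_lfc_abs_max` in
#' every stage x assay combination. Boundary values fail.
#'
#' @param lfc_min Minimum log2 fold change for a smOOPs call (default 1; a
#'   relaxed second-batch mode uses 0).
#' @param padj_max Adjusted-p ceiling for a smOOPs call (default 0.01).
#' @param control_padj_min Adjusted-p floor for controls (default 0.01).
#' @param control_lfc_abs_max Absolute LFC ceiling for controls (default 1.4).
#' @return A list of class `smoops_thresholds`.
#' @export
call_thresholds <- function(lfc_min = 1, padj_max = 0.01,
                            control_padj_min = 0.01,
                            control_lfc_abs_max = 1.4) {
  if (lfc_min < 0) abort("`lfc_min` must be >= 0")
  if (padj_max <= 0 || padj_max >= 1 || control_padj_min <= 0 || control_padj_min >= 1) {
    abort("padj bounds must lie in (0, 1)")
  }
  structure(
    list(lfc_min = lfc_min, padj_max = padj_max,
      control_padj_min = control_padj_min,
      control_lfc_abs_max = control_lfc_abs_max),
    class = "smoops_thresholds"
  )
}

#' Call smOOPs genes at one developmental stage
#'
#' A gene is a smOOPs gene when it passes `padj < padj_max` and
#' `lfc > lfc_min` in BOTH the semi-extractability and OOPS assays at the
#' given stage. Genes missing either assay are conservatively excluded.
#'
#' @param table Enrichment tibble with columns `gene_id`, `stage`, `assay`
#'   (`"semi"`/`"oops"`), `lfc`, `padj`.
#' @param thresholds A [call_thresholds()].
#' @param stage One of `"nPSC"`, `"pPSC"`, `"dPSC"` (or any stage present in
#'   the table).
#' @return A character vector of gene ids (sorted).
#' @export
call_smoops <- function(table, thresholds = call_thresholds(), stage) {
  if (!stage %in% table$stage) {
    if (nrow(table) == 0) return(character())
    abort(sprintf("unknown stage '%s'", stage))
  }
  table |>
    dplyr::filter(.data$stage == !!stage) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      pass = all(c("semi", "oops") %in% .data$assay) &&
        all(.data$padj < thresholds$padj_max & .data$lfc > thresholds$lfc_min),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$pass) |>
    dplyr::pull(.data$gene_id) |>
    sort()
}

#' Call the unified (all-stage) control gene set
#'
#' A gene is a common control when it satisfies `padj > control_padj_min` and
#' `|lfc| < control_lfc_abs_max` in every stage x assay combination present
#' in the table; genes missing any combination are excluded.
#'
#' @inheritParams call_smoops
#' @return A character vector of gene ids (sorted).
#' @export
call_common_controls <- function(table, thresholds = call_thresholds()) {
  combos <- dplyr::distinct(table, .data$stage, .data$assay)
  table |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(
      pass = dplyr::n() == nrow(combos) &&
        all(.data$padj > thresholds$control_padj_min &
          abs(.data$lfc) < thresholds$control_lfc_abs_max),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$pass) |>
    dplyr::pull(.data$gene_id) |>
    sort()
}

#' Granule-overlap enrichment of a smOOPs set
#'
#' One-sided (upper tail) hypergeometric test of the overlap between the
#' smOOPs set and each granule transcriptome, against the gene universe.
#' Granules are retained only when at least `min_exclusive` smOOPs belong to
#' that granule and to no other granule set.
#'
#' @param smoops Character vector of smOOPs gene ids (subset of `background`).
#' @param granules Named list of character vectors (granule gene sets).
#' @param background Character vector: the gene universe.
#' @param min_exclusive Minimum number of granule-exclusive smOOPs for a
#'   granule to be tested (default 10).
#' @return A tibble `granule`, `granule_size`, `overlap`, `exclusive`,
#'   `p_value`, `tested`.
#' @export
granule_enrichment <- function(smoops, granules, background, min_exclusive = 10) {
  if (length(background) == 0) abort("`background` must be non-empty")
  if (!all(smoops %in% background)) abort("`smoops` must be a subset of `background`")
  granules <- purrr::map(granules, intersect, background)
  empty <- names(granules)[lengths(granules) == 0]
  if (length(empty)) {
    warn(sprintf("granule set(s) empty after background restriction, skipped: %s",
      paste(empty, collapse = ", ")))
    granules <- granules[lengths(granules) > 0]
  }
  purrr::imap_dfr(granules, function(set, nm) {
    others <- unique(unlist(granules[setdiff(names(granules), nm)]))
    overlap <- intersect(smoops, set)
    exclusive <- setdiff(overlap, others)
    tested <- length(exclusive) >= min_exclusive
    p <- if (tested) {
      # upper-tail P(X >= overlap) for overlap ~ Hypergeom(|set|, N - |set|, |smoops|)
      phyper(length(overlap) - 1L, length(set),
        length(background) - length(set), length(smoops),
        lower.tail = FALSE)
    } else {
      NA_real_
    }
    tibble(granule = nm, granule_size = length(set), overlap = length(overlap),
      exclusive = length(exclusive), p_value = p, tested = tested)
  })
}

#' Biotype composition of a gene set
#'
#' @param genes Character vector of gene ids.
#' @param transcripts Tibble with `gene_id` and `biotype`.
#' @return A tibble `biotype`, `n`, `fraction` (fractions sum to 1 over the
#'   represented biotypes; empty set gives an empty tibble).
#' @export
biotype_breakdown <- function(genes, transcripts) {
  if (length(genes) == 0) {
    return(tibble(biotype = character(), n = integer(), fraction = double()))
  }
  missing <- setdiff(genes, transcripts$gene_id)
  if (length(missing)) {
    abort(sprintf("unknown gene(s): %s", paste(head(missing, 3), collapse = ", ")))
  }
  transcripts |>
    dplyr::filter(.data$gene_id %in% genes) |>
    dplyr::count(.data$biotype, name = "n") |>
    dplyr::mutate(fraction = .data$n / sum(.data$n))
}
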