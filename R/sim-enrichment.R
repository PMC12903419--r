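STAGES <- c("nPSC", "pPSC", "dPSC")
ASSAYS <- c("semi", "oops")

#' Generate a per-gene enrichment table across stages and assays
#'
#' For every gene x stage x assay combination, draws a class-conditional log2
#' fold change and computes an adjusted p value by simulating replicate-level
#' log-counts, applying a per-gene two-sample Welch test and
#' Benjamini-Hochberg correction across genes within each stage x assay. This
#' is a deliberately simple stand-in for a negative-binomial differential
#' enrichment model, adequate for planting calls in synthetic data; it is not
#' a differential-expression method.
#'
#' @param transcripts Tibble from [generate_transcripts()].
#' @param config A [sim_config()].
#' @return A tibble `gene_id`, `stage`, `assay`, `lfc`, `padj`.
#' @export
generate_enrichment_table <- function(transcripts, config) {
  validate_sim_config(config)
  ep <- config$enrichment_params
  with_seed(child_seed(config$seed, "enrichment"), {
    grid <- tidyr::expand_grid(
      gene_id = transcripts$gene_id, stage = STAGES, assay = ASSAYS
    ) |>
      dplyr::left_join(dplyr::select(transcripts, "gene_id", "class"), by = "gene_id")
    mu <- ifelse(grid$class == "positive", ep$lfc_mean_pos, ep$lfc_mean_neg)
    grid$lfc <- rnorm(nrow(grid), mu, ep$lfc_sd)
    nrep <- ep$n_replicates
    praw <- vapply(grid$lfc, function(l) {
      ctrl <- rnorm(nrep, 0, ep$noise_sd)
      trt <- rnorm(nrep, l, ep$noise_sd)
      if (ep$noise_sd == 0) {
        return(if (abs(l) > 0) 0 else 1)
      }
      t.test(trt, ctrl)$p.value
    }, numeric(1))
    grid |>
      dplyr::mutate(praw = praw) |>
      dplyr::group_by(.data$stage, .data$assay) |>
      dplyr::mutate(padj = p.adjust(.data$praw, method = "BH")) |>
      dplyr::ungroup() |>
      dplyr::select("gene_id", "stage", "assay", "lfc", "padj")
  })
}
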