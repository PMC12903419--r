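#' Generate hybrid (proximity-ligation) read records with a planted community
#'
#' Connects background gene pairs with probability `p_bg` and pairs inside
#' the focal set with probability `p_planted >= p_bg`; per-edge hybrid counts
#' are `1 + Poisson(count_lambda)`. A configurable fraction of records is
#' intramolecular (gene paired with itself).
#'
#' @param transcripts Tibble from [generate_transcripts()] (gene universe).
#' @param focal_set Character vector of gene ids forming the planted
#'   community; must be a subset of `transcripts$gene_id`.
#' @param config A [sim_config()].
#' @return A tibble `gene_a`, `gene_b`, `count`, `kind` (`"intra"`/`"inter"`).
#' @export
generate_hybrids <- function(transcripts, focal_set, config) {
  validate_sim_config(config)
  np <- config$network_params
  genes <- transcripts$gene_id
  if (!all(focal_set %in% genes)) {
    abort("`focal_set` must be a subset of the transcript gene ids")
  }
  with_seed(child_seed(config$seed, "hybrids"), {
    n <- length(genes)
    if (n < 2) {
      return(tibble(gene_a = character(), gene_b = character(),
        count = integer(), kind = character()))
    }
    pairs <- combn(genes, 2)
    focal <- pairs[1, ] %in% focal_set & pairs[2, ] %in% focal_set
    p <- ifelse(focal, np$p_planted, np$p_bg)
    keep <- runif(ncol(pairs)) < p
    inter <- tibble(
      gene_a = pairs[1, keep], gene_b = pairs[2, keep],
      count = 1L + rpois(sum(keep), np$count_lambda),
      kind = "inter"
    )
    n_intra <- rpois(1L, np$frac_intra * nrow(inter))
    intra_genes <- if (n_intra > 0) sample(genes, n_intra, replace = TRUE) else character()
    intra <- tibble(
      gene_a = intra_genes, gene_b = intra_genes,
      count = 1L + rpois(n_intra, np$count_lambda),
      kind = "intra"
    )
    dplyr::bind_rows(inter, intra)
  })
}
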