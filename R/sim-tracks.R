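TRACK_NAMES_BASE <- c("iclip", "m6a", "paris_intra", "paris_inter", "rnafold")

#' Generate per-transcript positional feature tracks
#'
#' Simulates the positional data layers used for encoding: cumulative RBP
#' crosslink counts (`iclip`), m6A site counts (`m6a`), intra- and
#' intermolecular duplex counts (`paris_intra`, `paris_inter`), a binary
#' predicted-pairedness track (`rnafold`) and a panel of binary per-RBP peak
#' tracks (`postar3_<rbp>`). Count tracks scale with expression (TPM); the
#' positive class receives the configured 3'UTR crosslink enrichment, CDS
#' duplex enrichment and informative-RBP peak enrichment.
#'
#' @param transcripts Tibble from [generate_transcripts()].
#' @param config A [sim_config()].
#' @return A tibble with columns `gene_id`, `track`, `values` (list-column of
#'   per-position numeric vectors, length-matched to the transcript).
#' @export
generate_feature_tracks <- function(transcripts, config) {
  validate_sim_config(config)
  tp <- config$track_params
  known <- c("iclip_rate", "iclip_utr3_enrichment", "m6a_rate", "paris_intra_rate",
    "paris_intra_cds_enrichment", "paris_inter_rate", "rnafold_p", "rbp_panel",
    "postar3_peak_rate", "postar3_peak_width", "rbp_informative",
    "rbp_informative_enrichment")
  extra <- setdiff(names(tp), known)
  if (length(extra)) {
    abort(sprintf("unknown track parameter(s): %s", paste(extra, collapse = ", ")),
      class = "smoopr_config_error")
  }
  with_seed(child_seed(config$seed, "tracks"), {
    rows <- vector("list", nrow(transcripts) * (5 + length(tp$rbp_panel)))
    k <- 0L
    for (i in seq_len(nrow(transcripts))) {
      tx <- transcripts[i, ]
      L <- tx$length
      pos_class <- tx$class == "positive"
      reg <- region_of_positions(tx)
      # iclip: Poisson per nt, rate scaled by TPM; positive 3'UTR enriched
      rate <- rep(tp$iclip_rate * tx$tpm, L)
      if (pos_class) rate[reg == "utr3" | reg == "whole"] <- rate[reg == "utr3" | reg == "whole"] * tp$iclip_utr3_enrichment
      tracks <- list(iclip = rpois(L, rate))
      tracks$m6a <- rpois(L, tp$m6a_rate * tx$tpm)
      ri <- rep(tp$paris_intra_rate * tx$tpm, L)
      if (pos_class) ri[reg == "cds" | reg == "whole"] <- ri[reg == "cds" | reg == "whole"] * tp$paris_intra_cds_enrichment
      tracks$paris_intra <- rpois(L, ri)
      tracks$paris_inter <- rpois(L, tp$paris_inter_rate * tx$tpm)
      tracks$rnafold <- rbinom(L, 1L, tp$rnafold_p)
      for (rbp in tp$rbp_panel) {
        lambda <- tp$postar3_peak_rate * L / 1000
        if (pos_class && rbp %in% tp$rbp_informative) lambda <- lambda * tp$rbp_informative_enrichment
        n_peaks <- rpois(1L, lambda)
        v <- integer(L)
        if (n_peaks > 0 && L > 1) {
          starts <- sample.int(L, min(n_peaks, L), replace = TRUE)
          for (s in starts) v[s:min(L, s + tp$postar3_peak_width - 1L)] <- 1L
        }
        tracks[[paste0("postar3_", rbp)]] <- v
      }
      for (nm in names(tracks)) {
        k <- k + 1L
        rows[[k]] <- tibble(gene_id = tx$gene_id, track = nm,
          values = list(as.numeric(tracks[[nm]])))
      }
    }
    dplyr::bind_rows(rows[seq_len(k)])
  })
}

# Fetch one track vector for one gene.
get_track <- function(tracks, gene, name) {
  v <- tracks$values[tracks$gene_id == gene & tracks$track == name]
  if (length(v) != 1) abort(sprintf("track '%s' missing for gene %s", name, gene))
  v[[1]]
}
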