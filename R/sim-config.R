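#' Simulation configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic transcriptome: cohort size, the
#' fraction of condensation-prone ("positive") genes, per-region transcript
#' length distributions, class- and region-specific nucleotide composition,
#' positional track intensities, proximity-network edge probabilities and
#' enrichment-table effect sizes. The defaults plant the signal structure the
#' downstream modules are designed to detect: a C-rich CDS and longer
#' transcripts in the positive class, 3'UTR-enriched crosslinking, a dense
#' planted interaction community, and a two-assay log-fold-change shift.
#'
#' @param seed Integer seed; together with the config it fully determines
#'   every generated object.
#' @param n_genes Number of genes in the cohort.
#' @param frac_positive Fraction of genes in the positive (condensation-prone)
#'   class.
#' @param frac_noncoding Fraction of genes drawn as non-coding (lncRNA/TEC)
#'   biotypes; the rest are protein coding.
#' @param region_length_params Named list with elements `utr5`, `cds`, `utr3`,
#'   each `c(meanlog, sdlog)` of a log-normal length distribution
#'   (nucleotides), plus `positive_cds_factor` and `positive_utr3_factor`
#'   multiplying the positive-class median CDS/3'UTR lengths (positive-class
#'   transcripts are longer on average, with the CDS the primary driver).
#' @param composition_params Named list with per-class, per-region nucleotide
#'   probabilities in A,C,G,T order: `positive` and `negative`, each a list
#'   with `utr5`, `cds`, `utr3`; each vector must sum to 1.
#' @param track_params Positional track intensities: `iclip_rate` (expected
#'   crosslinks per nucleotide per TPM), `iclip_utr3_enrichment`
#'   (multiplicative 3'UTR crosslink enrichment in the positive class),
#'   `m6a_rate`, `paris_intra_rate`, `paris_inter_rate` (per-nucleotide count
#'   rates per TPM), `paris_intra_cds_enrichment` (positive class),
#'   `rnafold_p` (Bernoulli probability of the binary pairedness track),
#'   `rbp_panel` (character vector of RBP names for the binary peak panel),
#'   `postar3_peak_rate` (expected peaks per kilobase), `postar3_peak_width`,
#'   `rbp_informative` (panel members whose peak rate is multiplied by
#'   `rbp_informative_enrichment` in the positive class).
#' @param network_params `p_bg` background gene-pair edge probability,
#'   `p_planted` edge probability inside the planted (focal) community,
#'   `count_lambda` Poisson rate so per-edge hybrid counts are
#'   `1 + Poisson(count_lambda)`, `frac_intra` expected fraction of
#'   intramolecular records.
#' @param enrichment_params `lfc_mean_pos`, `lfc_mean_neg`, `lfc_sd` for the
#'   class-conditional log2 fold change draw, `n_replicates` simulated
#'   replicates per condition and `noise_sd` replicate-level log-count noise
#'   used by the Welch-test stand-in that produces adjusted p values.
#' @param tpm_meanlog,tpm_sdlog Log-normal expression (TPM) parameters.
#'
#' @return A validated list of class `smoops_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50)
#' tx <- generate_transcripts(cfg)
sim_config <- function(seed = 1L,
                       n_genes = 400L,
                       frac_positive = 0.35,
                       frac_noncoding = 0.1,
                       region_length_params = list(
                         utr5 = c(meanlog = log(35), sdlog = 0.25),
                         cds = c(meanlog = log(150), sdlog = 0.18),
                         utr3 = c(meanlog = log(100), sdlog = 0.22),
                         positive_cds_factor = 1.25,
                         positive_utr3_factor = 1.15
                       ),
                       composition_params = list(
                         positive = list(
                           utr5 = c(A = 0.24, C = 0.30, G = 0.22, T = 0.24),
                           cds = c(A = 0.18, C = 0.40, G = 0.20, T = 0.22),
                           utr3 = c(A = 0.26, C = 0.26, G = 0.20, T = 0.28)
                         ),
                         negative = list(
                           utr5 = c(A = 0.27, C = 0.23, G = 0.22, T = 0.28),
                           cds = c(A = 0.27, C = 0.23, G = 0.22, T = 0.28),
                           utr3 = c(A = 0.27, C = 0.23, G = 0.22, T = 0.28)
                         )
                       ),
                       track_params = list(
                         iclip_rate = 0.02,
                         iclip_utr3_enrichment = 2,
                         m6a_rate = 0.004,
                         paris_intra_rate = 0.01,
                         paris_intra_cds_enrichment = 2,
                         paris_inter_rate = 0.005,
                         rnafold_p = 0.5,
                         rbp_panel = paste0("RBP", seq_len(8)),
                         postar3_peak_rate = 2,
                         postar3_peak_width = 8,
                         rbp_informative = "RBP1",
                         rbp_informative_enrichment = 3
                       ),
                       network_params = list(
                         p_bg = 0.02,
                         p_planted = 0.25,
                         count_lambda = 1,
                         frac_intra = 0.1
                       ),
                       enrichment_params = list(
                         lfc_mean_pos = 2,
                         lfc_mean_neg = 0,
                         lfc_sd = 0.3,
                         n_replicates = 4,
                         noise_sd = 0.15
                       ),
                       tpm_meanlog = log(25),
                       tpm_sdlog = 0.8) {
  cfg <- list(
    seed = as.integer(seed), n_genes = as.integer(n_genes),
    frac_positive = frac_positive, frac_noncoding = frac_noncoding,
    region_length_params = region_length_params,
    composition_params = composition_params,
    track_params = track_params,
    network_params = network_params,
    enrichment_params = enrichment_params,
    tpm_meanlog = tpm_meanlog, tpm_sdlog = tpm_sdlog
  )
  validate_sim_config(cfg)
  structure(cfg, class = "smoops_sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 0) abort("`n_genes` must be non-negative", class = "smoopr_config_error")
  if (cfg$frac_positive < 0 || cfg$frac_positive > 1) {
    abort("`frac_positive` must lie in [0, 1]", class = "smoopr_config_error")
  }
  for (cls in c("positive", "negative")) {
    for (reg in c("utr5", "cds", "utr3")) {
      p <- cfg$composition_params[[cls]][[reg]]
      if (length(p) != 4 || any(p < 0) || any(p > 1)) {
        abort(sprintf("composition for %s/%s must be 4 probabilities in [0,1]", cls, reg),
          class = "smoopr_config_error")
      }
      if (abs(sum(p) - 1) > 1e-8) {
        abort(sprintf("composition for %s/%s must sum to 1", cls, reg),
          class = "smoopr_config_error")
      }
    }
  }
  rl <- cfg$region_length_params
  for (reg in c("utr5", "cds", "utr3")) {
    if (exp(rl[[reg]][["meanlog"]]) <= 0) abort("region lengths must be positive", class = "smoopr_config_error")
  }
  np <- cfg$network_params
  if (np$p_planted < np$p_bg) {
    abort("`p_planted` must be >= `p_bg`", class = "smoopr_config_error")
  }
  if (any(c(np$p_bg, np$p_planted) < 0) || any(c(np$p_bg, np$p_planted) > 1)) {
    abort("edge probabilities must lie in [0, 1]", class = "smoopr_config_error")
  }
  invisible(cfg)
}

#' Read a pipeline configuration from a YAML file
#'
#' A serialized config (seed included) fully determines every stochastic
#' output of the pipeline. Top-level keys override the corresponding
#' [sim_config()] arguments.
#'
#' @param path Path to a YAML file.
#' @return A `smoops_sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("reading YAML configs requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  defaults <- formals(sim_config)
  known <- intersect(names(raw), names(defaults))
  do.call(sim_config, raw[known])
}
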