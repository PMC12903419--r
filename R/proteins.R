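# Monoisotopic residue masses (Da); protein mass = sum + water.
AA_MONO_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
WATER_MONO <- 18.01056
AA_LETTERS <- names(AA_MONO_MASS)

# IUPAC-conventional physicochemical classes.
AA_CLASSES <- list(
  charged = c("D", "E", "K", "R", "H"),
  polar = c("S", "T", "N", "Q", "Y", "C"),
  hydrophobic = c("A", "V", "L", "I", "M", "F", "W"),
  special = c("G", "P")
)

translate_one <- function(cds, gene_id = "?") {
  if (nchar(cds) %% 3 != 0) {
    abort(sprintf("CDS length for %s is not a multiple of 3", gene_id))
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(gsub("U", "T", toupper(cds))),
    if.fuzzy.codon = "X"
  ))
  # strip terminal stop; truncate at any internal stop
  aa <- sub("\\*$", "", aa)
  star <- regexpr("*", aa, fixed = TRUE)
  if (star > 0) {
    warn(sprintf("internal stop codon in %s; translation truncated", gene_id))
    aa <- substr(aa, 1L, star - 1L)
  }
  aa
}

#' Translate coding sequences into protein records
#'
#' Standard genetic code; the terminal stop is removed and an internal stop
#' truncates the translation with a warning. Mass is computed from
#' monoisotopic residue masses plus water.
#'
#' @param transcripts Tibble from [generate_transcripts()] (protein-coding
#'   rows are translated; others are skipped).
#' @return A tibble `gene_id`, `protein`, `length`, `mass`.
#' @export
translate_cds <- function(transcripts) {
  coding <- dplyr::filter(transcripts, .data$biotype == "protein_coding")
  prot <- purrr::map2_chr(coding$sequence, seq_len(nrow(coding)), function(s, i) {
    cds <- substr(s, coding$utr5_len[i] + 1L, coding$utr5_len[i] + coding$cds_len[i])
    translate_one(cds, coding$gene_id[i])
  })
  tibble(
    gene_id = coding$gene_id, protein = prot, length = nchar(prot),
    mass = purrr::map_dbl(prot, function(p) {
      if (nchar(p) == 0) return(WATER_MONO)
      sum(AA_MONO_MASS[strsplit(p, "")[[1]]]) + WATER_MONO
    })
  )
}

#' Generate synthetic protein records with planted disorder annotations
#'
#' Translates the coding transcripts (class-conditional codon usage in the
#' synthetic cohort induces the planted amino-acid shifts) and draws
#' class-conditional intrinsically-disordered-region (IDR) annotations: each
#' protein's disorder fraction is drawn around the class mean and realised as
#' 1-3 non-overlapping intervals.
#'
#' @param transcripts Tibble from [generate_transcripts()].
#' @param config A [sim_config()].
#' @param idr_frac_positive,idr_frac_negative Mean annotated disorder fraction
#'   per class.
#' @param idr_conc Beta concentration of the per-protein disorder fraction
#'   around the class mean (larger = tighter).
#' @return A tibble `gene_id`, `class`, `protein`, `length`, `mass`,
#'   `idr_intervals` (list-column of 0-based half-open two-column matrices).
#' @export
generate_proteins <- function(transcripts, config,
                              idr_frac_positive = 0.45,
                              idr_frac_negative = 0.2,
                              idr_conc = 30) {
  validate_sim_config(config)
  prot <- translate_cds(transcripts) |>
    dplyr::left_join(dplyr::select(transcripts, "gene_id", "class"), by = "gene_id")
  with_seed(child_seed(config$seed, "proteins"), {
    prot$idr_intervals <- purrr::map2(prot$length, prot$class, function(L, cls) {
      f <- if (cls == "positive") idr_frac_positive else idr_frac_negative
      frac <- rbeta(1, f * idr_conc, (1 - f) * idr_conc)
      total <- round(frac * L)
      if (total < 1 || L < 4) return(matrix(integer(), ncol = 2))
      k <- sample(1:3, 1L)
      k <- min(k, total)
      lens <- as.vector(stats::rmultinom(1, total, rep(1 / k, k)))
      lens <- lens[lens > 0]
      # place intervals left to right without overlap
      slack <- L - sum(lens)
      gaps <- if (length(lens) > 0) sort(sample.int(slack + 1L, length(lens), replace = TRUE)) - 1L else integer()
      start <- cumsum(c(0L, head(lens, -1L))) + gaps
      cbind(start = as.integer(start), end = as.integer(start + lens))
    })
    dplyr::relocate(prot, "gene_id", "class")
  })
}

#' Per-amino-acid enrichment between protein groups
#'
#' Computes each protein's relative amino-acid frequencies, then per residue
#' the log2 fold change of the group mean over the background mean and a
#' two-sided Welch t-test on the per-protein frequencies.
#'
#' @param group,background Protein tibbles (need a `protein` column).
#' @return A tibble `aa`, `class` (physicochemical group), `mean_group`,
#'   `mean_background`, `log2fc`, `statistic`, `p_value`.
#' @export
aa_enrichment <- function(group, background) {
  if (nrow(group) == 0 || nrow(background) == 0) {
    abort("both protein groups must be non-empty")
  }
  freq_mat <- function(prot) {
    t(vapply(prot, function(p) {
      if (nchar(p) == 0) return(setNames(rep(NA_real_, 20), AA_LETTERS))
      tab <- table(factor(strsplit(p, "")[[1]], levels = AA_LETTERS))
      as.numeric(tab) / nchar(p)
    }, numeric(20)))
  }
  fg <- freq_mat(group$protein)
  bg <- freq_mat(background$protein)
  colnames(fg) <- colnames(bg) <- AA_LETTERS
  cls_of <- function(aa) {
    hit <- names(AA_CLASSES)[vapply(AA_CLASSES, function(v) aa %in% v, logical(1))]
    if (length(hit)) hit[1] else NA_character_
  }
  purrr::map_dfr(AA_LETTERS, function(aa) {
    mg <- mean(fg[, aa], na.rm = TRUE)
    mb <- mean(bg[, aa], na.rm = TRUE)
    if (!is.finite(mb) || mb == 0) {
      return(tibble(aa = aa, class = cls_of(aa), mean_group = mg,
        mean_background = mb, log2fc = NA_real_,
        statistic = NA_real_, p_value = NA_real_))
    }
    tt <- welch_safe(fg[, aa], bg[, aa])
    tibble(
      aa = aa, class = cls_of(aa), mean_group = mg, mean_background = mb,
      log2fc = log2(mg / mb),
      statistic = unname(tt$statistic), p_value = tt$p.value
    )
  })
}

#' C or A content of the codons encoding an amino acid
#'
#' Fraction of C (or A) nucleotides among all codon positions of the
#' standard-code codons for the residue.
#'
#' @param aa Single-letter amino-acid code.
#' @param mode `"C"` or `"A"`.
#' @return A fraction in `[0, 1]`.
#' @export
#' @examples
#' codon_ca_content("P", "C") # proline: 9/12
codon_ca_content <- function(aa, mode = c("C", "A")) {
  mode <- match.arg(mode)
  aa <- toupper(aa)
  if (!aa %in% AA_LETTERS) abort(sprintf("unknown residue '%s'", aa))
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc == aa]
  nts <- strsplit(paste(codons, collapse = ""), "")[[1]]
  mean(nts == mode)
}

merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(matrix(integer(), ncol = 2))
  r <- IRanges::reduce(IRanges::IRanges(start = iv[, 1] + 1L, end = iv[, 2]))
  cbind(IRanges::start(r) - 1L, IRanges::end(r))
}

disorder_fraction <- function(iv, len) {
  m <- merge_intervals(iv)
  if (nrow(m) == 0 || len == 0) return(0)
  sum(m[, 2] - m[, 1]) / len
}

#' Disorder, mass and condensate-propensity statistics between protein groups
#'
#' Per group: percentage of proteins with at least one annotated IDR, the
#' per-protein disorder fraction (merged interval length over protein
#' length), mass and optional precomputed condensate-propensity scores
#' (`picnic_score` column). Comparisons: two-sided Wilcoxon rank-sum for the
#' disorder fraction, two-sided Welch t-test for mass and for the optional
#' scores.
#'
#' @param group,background Protein tibbles from [generate_proteins()] (or with
#'   the same columns).
#' @return A list with `summary` (per-group tibble) and `tests` (tibble of
#'   comparisons).
#' @export
disorder_stats <- function(group, background) {
  one <- function(df, label) {
    frac <- purrr::map2_dbl(df$idr_intervals, df$length, disorder_fraction)
    tibble(
      group = label, n = nrow(df),
      pct_with_idr = 100 * mean(frac > 0),
      mean_disorder_fraction = mean(frac),
      median_mass = median(df$mass)
    )
  }
  fr_g <- purrr::map2_dbl(group$idr_intervals, group$length, disorder_fraction)
  fr_b <- purrr::map2_dbl(background$idr_intervals, background$length, disorder_fraction)
  tests <- dplyr::bind_rows(
    {
      wt <- suppressWarnings(wilcox.test(fr_g, fr_b)) # ties fall back to the normal approximation
      tibble(quantity = "disorder_fraction", test = "wilcoxon",
        statistic = unname(wt$statistic), p_value = wt$p.value)
    },
    {
      tt <- welch_safe(group$mass, background$mass)
      tibble(quantity = "mass", test = "welch",
        statistic = unname(tt$statistic), p_value = tt$p.value)
    }
  )
  if ("picnic_score" %in% names(group) && "picnic_score" %in% names(background)) {
    tt <- welch_safe(group$picnic_score, background$picnic_score)
    tests <- dplyr::bind_rows(tests, tibble(quantity = "picnic_score",
      test = "welch", statistic = unname(tt$statistic), p_value = tt$p.value))
  }
  list(
    summary = dplyr::bind_rows(one(group, "group"), one(background, "background")),
    tests = tests
  )
}
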