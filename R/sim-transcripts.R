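STOP_CODONS <- c("TAA", "TAG", "TGA")

# Draw a log-normal length, at least `min` nucleotides, truncated at the
# 97.5th percentile so rare extreme draws do not dominate the padded length.
draw_len <- function(n, meanlog, sdlog, min = 10L) {
  cap <- stats::qlnorm(0.975, meanlog, sdlog)
  pmax(min, as.integer(round(pmin(cap, rlnorm(n, meanlog, sdlog)))))
}

# Sample a nucleotide string of length n from probabilities p (A,C,G,T).
draw_seq <- function(n, p) {
  if (n <= 0) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# Sample a CDS: ATG start, internal codons free of stops, terminal stop.
draw_cds <- function(n_codons, p) {
  if (n_codons < 2) n_codons <- 2L
  inner <- n_codons - 2L
  codons <- character(inner)
  if (inner > 0) {
    for (i in seq_len(inner)) {
      repeat {
        cod <- draw_seq(3L, p)
        if (!cod %in% STOP_CODONS) break
      }
      codons[i] <- cod
    }
  }
  paste0("ATG", paste(codons, collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate a synthetic transcript cohort with planted class structure
#'
#' Draws `n_genes` transcripts in two classes. Positive-class (condensation
#' prone) transcripts use class-specific regional nucleotide probabilities
#' (by default a C-rich CDS) and are longer on average (CDS-driven). A
#' configurable fraction of genes is non-coding (lncRNA/TEC biotypes, no
#' region structure). Each gene is placed on its own contig with 1-4 exons so
#' genomic interval projection can be exercised.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per gene: `gene_id`, `biotype`, `class`
#'   (planted truth), `chrom`, `strand`, `exon_starts`/`exon_ends`
#'   (list-columns of 0-based half-open genomic intervals), `utr5_len`,
#'   `cds_len`, `utr3_len`, `length`, `sequence` (DNA alphabet; use
#'   [rna_sequence()] to render U), `tpm`.
#' @export
generate_transcripts <- function(config) {
  validate_sim_config(config)
  n <- config$n_genes
  if (n == 0L) {
    return(tibble(
      gene_id = character(), biotype = character(), class = character(),
      chrom = character(), strand = character(),
      exon_starts = list(), exon_ends = list(),
      utr5_len = integer(), cds_len = integer(), utr3_len = integer(),
      length = integer(), sequence = character(), tpm = double()
    ))
  }
  with_seed(child_seed(config$seed, "transcripts"), {
    n_pos <- round(n * config$frac_positive)
    class <- c(rep("positive", n_pos), rep("negative", n - n_pos))
    n_nc <- round(n * config$frac_noncoding)
    # non-coding genes spread over both classes in proportion
    nc_idx <- if (n_nc > 0) {
      c(
        head(which(class == "positive"), round(n_nc * config$frac_positive)),
        head(which(class == "negative"), n_nc - round(n_nc * config$frac_positive))
      )
    } else {
      integer()
    }
    biotype <- rep("protein_coding", n)
    biotype[nc_idx] <- sample(c("lncRNA", "TEC"), length(nc_idx), replace = TRUE)

    rl <- config$region_length_params
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      cls <- class[i]
      comp <- config$composition_params[[cls]]
      cds_meanlog <- rl$cds[["meanlog"]] +
        if (cls == "positive") log(rl$positive_cds_factor) else 0
      utr3_meanlog <- rl$utr3[["meanlog"]] +
        if (cls == "positive") log(rl$positive_utr3_factor) else 0
      if (biotype[i] == "protein_coding") {
        u5 <- draw_len(1L, rl$utr5[["meanlog"]], rl$utr5[["sdlog"]])
        n_codons <- max(2L, round(draw_len(1L, cds_meanlog, rl$cds[["sdlog"]], min = 6L) / 3))
        u3 <- draw_len(1L, utr3_meanlog, rl$utr3[["sdlog"]])
        seq <- paste0(
          draw_seq(u5, comp$utr5),
          draw_cds(n_codons, comp$cds),
          draw_seq(u3, comp$utr3)
        )
        cds_len <- 3L * n_codons
      } else {
        # non-coding: one region drawn with the 3'UTR-like composition
        len <- draw_len(1L, cds_meanlog, rl$cds[["sdlog"]], min = 60L)
        seq <- draw_seq(len, comp$utr3)
        u5 <- NA_integer_; cds_len <- NA_integer_; u3 <- NA_integer_
      }
      len <- nchar(seq)
      # split into 1-4 exons on a private contig with random intron gaps
      n_exons <- sample(1:4, 1L)
      if (n_exons >= len) n_exons <- 1L
      cuts <- sort(sample(seq_len(len - 1L), n_exons - 1L))
      exon_len <- diff(c(0L, cuts, len))
      introns <- if (n_exons > 1) sample(50:500, n_exons - 1L, replace = TRUE) else integer()
      starts <- integer(n_exons); ends <- integer(n_exons)
      pos <- sample(100:1000, 1L)
      for (e in seq_len(n_exons)) {
        starts[e] <- pos
        ends[e] <- pos + exon_len[e]
        pos <- ends[e] + if (e < n_exons) introns[e] else 0L
      }
      rows[[i]] <- tibble(
        gene_id = sprintf("G%04d", i), biotype = biotype[i], class = cls,
        chrom = sprintf("ctg_G%04d", i), strand = "+",
        exon_starts = list(starts), exon_ends = list(ends),
        utr5_len = u5, cds_len = cds_len, utr3_len = u3,
        length = len, sequence = seq,
        tpm = rlnorm(1, config$tpm_meanlog, config$tpm_sdlog)
      )
    }
    dplyr::bind_rows(rows)
  })
}

#' Render a transcript sequence with the RNA alphabet
#'
#' Sequences are stored with T internally; U and T are treated as synonyms
#' throughout the package.
#'
#' @param x A character vector of nucleotide sequences.
#' @return The same sequences with T replaced by U.
#' @export
rna_sequence <- function(x) gsub("T", "U", toupper(x), fixed = TRUE)

# Region label per transcript position (protein-coding only).
region_of_positions <- function(tx_row) {
  if (is.na(tx_row$utr5_len)) {
    return(rep("whole", tx_row$length))
  }
  rep(c("utr5", "cds", "utr3"), c(tx_row$utr5_len, tx_row$cds_len, tx_row$utr3_len))
}

# 0-based half-open [start, end) of a named region in transcript coordinates.
region_bounds <- function(tx_row, region) {
  u5 <- tx_row$utr5_len; cds <- tx_row$cds_len
  switch(region,
    utr5 = c(0L, u5),
    cds = c(u5, u5 + cds),
    utr3 = c(u5 + cds, tx_row$length),
    whole = c(0L, tx_row$length),
    abort(sprintf("unknown region '%s'", region))
  )
}
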