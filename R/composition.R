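#' Region-aware binning scheme
#'
#' `by_region` divides coding transcripts into 10 bins over the 5'UTR and 50
#' bins each over the CDS and 3'UTR (110 bins total, labelled by region);
#' `whole` divides the full transcript into 100 bins.
#'
#' @param mode `"by_region"` or `"whole"`.
#' @param utr5_bins,cds_bins,utr3_bins,whole_bins Bin counts.
#' @return A list of class `smoops_binning`.
#' @export
binning_scheme <- function(mode = c("by_region", "whole"),
                           utr5_bins = 10L, cds_bins = 50L, utr3_bins = 50L,
                           whole_bins = 100L) {
  mode <- match.arg(mode)
  if (any(c(utr5_bins, cds_bins, utr3_bins, whole_bins) < 1)) {
    abort("bin counts must be positive")
  }
  structure(
    list(mode = mode, utr5_bins = utr5_bins, cds_bins = cds_bins,
      utr3_bins = utr3_bins, whole_bins = whole_bins),
    class = "smoops_binning"
  )
}

# Mean of v within each of nb proportional bins; for vectors shorter than
# nb each bin takes its nearest position's value, so no bin is ever empty.
bin_means <- function(v, nb) {
  L <- length(v)
  if (L >= nb) {
    as.numeric(tapply(v, bin_of_positions(L, nb), mean))
  } else {
    v[pmin(L, floor((seq_len(nb) - 0.5) * L / nb) + 1L)]
  }
}

scheme_bin_labels <- function(scheme) {
  if (scheme$mode == "whole") {
    paste0("whole_", seq_len(scheme$whole_bins))
  } else {
    c(paste0("utr5_", seq_len(scheme$utr5_bins)),
      paste0("cds_", seq_len(scheme$cds_bins)),
      paste0("utr3_", seq_len(scheme$utr3_bins)))
  }
}

# Apply bin_means per region of a per-position vector under a scheme;
# returns NULL when the transcript cannot be binned (non-coding, by_region).
scheme_bin_means <- function(tx_row, v, scheme) {
  if (scheme$mode == "whole") return(bin_means(v, scheme$whole_bins))
  if (is.na(tx_row$utr5_len)) return(NULL)
  u5 <- tx_row$utr5_len
  cds <- tx_row$cds_len
  c(
    bin_means(v[seq_len(u5)], scheme$utr5_bins),
    bin_means(v[u5 + seq_len(cds)], scheme$cds_bins),
    bin_means(v[(u5 + cds + 1):tx_row$length], scheme$utr3_bins)
  )
}

# Per-bin nucleotide frequency matrix (bins x 4) for one transcript.
per_bin_nt_freq <- function(tx_row, scheme) {
  chars <- strsplit(gsub("U", "T", toupper(tx_row$sequence)), "")[[1]]
  cols <- purrr::map(c("A", "C", "G", "T"), function(nt) {
    scheme_bin_means(tx_row, as.numeric(chars == nt), scheme)
  })
  if (is.null(cols[[1]])) return(NULL)
  out <- do.call(cbind, cols)
  dimnames(out) <- list(scheme_bin_labels(scheme), c("A", "C", "G", "T"))
  out
}

#' Per-bin nucleotide composition difference between two transcript groups
#'
#' Per transcript, the frequency of each nucleotide within each bin; the
#' difference is the group mean minus the control mean per bin. Differences
#' across the four nucleotides sum to zero in every bin. Non-coding
#' transcripts are excluded (with a count) under the `by_region` scheme.
#'
#' @param transcripts Transcript tibble.
#' @param group,control Character vectors of gene ids.
#' @param scheme A [binning_scheme()].
#' @return A tibble `bin`, `region`, `nucleotide`, `mean_group`,
#'   `mean_control`, `diff`; attribute `n_excluded` counts skipped
#'   transcripts.
#' @export
binned_nucleotide_diff <- function(transcripts, group, control,
                                   scheme = binning_scheme("by_region")) {
  grp_stats <- function(ids) {
    rows <- transcripts[transcripts$gene_id %in% ids, ]
    mats <- purrr::map(seq_len(nrow(rows)), function(i) per_bin_nt_freq(rows[i, ], scheme))
    excl <- sum(purrr::map_lgl(mats, is.null))
    mats <- purrr::compact(mats)
    if (length(mats) == 0) abort("no transcripts usable under this scheme")
    list(mean = Reduce(`+`, mats) / length(mats), n_excluded = excl)
  }
  g <- grp_stats(group)
  ctl <- grp_stats(control)
  bins <- rownames(g$mean)
  out <- tidyr::expand_grid(bin = bins, nucleotide = c("A", "C", "G", "T")) |>
    dplyr::mutate(
      region = sub("_.*", "", .data$bin),
      mean_group = purrr::map2_dbl(.data$bin, .data$nucleotide, ~ g$mean[.x, .y]),
      mean_control = purrr::map2_dbl(.data$bin, .data$nucleotide, ~ ctl$mean[.x, .y]),
      diff = .data$mean_group - .data$mean_control
    ) |>
    dplyr::relocate("bin", "region", "nucleotide")
  attr(out, "n_excluded") <- c(group = g$n_excluded, control = ctl$n_excluded)
  out
}

ALL_TRIPLETS <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
  c("A", "C", "G", "T"))[, 3:1], 1, paste, collapse = "")

# Overlapping 3-mer frequencies of a sequence (64-vector summing to 1).
triplet_freqs <- function(sequence) {
  s <- gsub("U", "T", toupper(sequence))
  L <- nchar(s)
  if (L < 3) return(NULL)
  tri <- substring(s, 1:(L - 2), 3:L)
  tab <- table(factor(tri, levels = ALL_TRIPLETS))
  as.numeric(tab) / (L - 2)
}

#' Triplet (3-mer) frequency difference between transcript groups
#'
#' Overlapping 3-mer frequencies per transcript (windows at stride 1, L-2 of
#' them), averaged per group; difference = group mean minus control mean.
#' With a `by_region` scheme the analysis is repeated within each region of
#' coding transcripts.
#'
#' @inheritParams binned_nucleotide_diff
#' @param scheme Either `NULL`/`"whole"`-mode scheme (whole-transcript
#'   3-mers) or a `by_region` scheme.
#' @return A tibble `region`, `triplet` (U-alphabet), `mean_group`,
#'   `mean_control`, `diff`.
#' @export
triplet_freq_diff <- function(transcripts, group, control, scheme = NULL) {
  by_region <- !is.null(scheme) && scheme$mode == "by_region"
  region_seqs <- function(ids) {
    rows <- transcripts[transcripts$gene_id %in% ids, ]
    if (!by_region) {
      return(list(whole = rows$sequence))
    }
    rows <- rows[!is.na(rows$utr5_len), ]
    list(
      utr5 = substr(rows$sequence, 1, rows$utr5_len),
      cds = substr(rows$sequence, rows$utr5_len + 1, rows$utr5_len + rows$cds_len),
      utr3 = substr(rows$sequence, rows$utr5_len + rows$cds_len + 1, rows$length)
    )
  }
  gs <- region_seqs(group)
  cs <- region_seqs(control)
  purrr::imap_dfr(gs, function(gseqs, reg) {
    fg <- purrr::compact(purrr::map(gseqs, triplet_freqs))
    fc <- purrr::compact(purrr::map(cs[[reg]], triplet_freqs))
    if (length(fg) == 0 || length(fc) == 0) {
      return(tibble(region = character(), triplet = character(),
        mean_group = double(), mean_control = double(), diff = double()))
    }
    mg <- Reduce(`+`, fg) / length(fg)
    mc <- Reduce(`+`, fc) / length(fc)
    tibble(
      region = reg, triplet = gsub("T", "U", ALL_TRIPLETS),
      mean_group = mg, mean_control = mc, diff = mg - mc
    )
  })
}

#' Binned track medians with bootstrap confidence intervals
#'
#' Per transcript, the mean signal within each bin; per bin, the median
#' across transcripts with a percentile bootstrap 95 percent CI over
#' transcripts (1000 resamples by default), for the group and the control.
#'
#' @param transcripts Transcript tibble.
#' @param tracks Normalised track tibble.
#' @param track Track name (e.g. `"iclip"`).
#' @param group,control Gene id vectors (>= 3 usable transcripts each).
#' @param scheme A [binning_scheme()].
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return A tibble `set`, `bin`, `region`, `median`, `ci_lo`, `ci_hi`, `n`.
#' @export
binned_signal_median <- function(transcripts, tracks, track, group, control,
                                 scheme = binning_scheme("by_region"),
                                 n_boot = 1000, seed = 1L) {
  group_bin_means <- function(ids) {
    rows <- transcripts[transcripts$gene_id %in% ids, ]
    mats <- purrr::map(seq_len(nrow(rows)), function(i) {
      v <- get_track(tracks, rows$gene_id[i], track)
      scheme_bin_means(rows[i, ], v, scheme)
    })
    m <- do.call(rbind, purrr::compact(mats))
    if (is.null(m) || nrow(m) < 3) abort("fewer than 3 usable transcripts in a group")
    m
  }
  bins <- scheme_bin_labels(scheme)
  with_seed(seed, {
    purrr::imap_dfr(list(group = group_bin_means(group), control = group_bin_means(control)),
      function(m, label) {
        boots <- matrix(0, n_boot, ncol(m))
        for (b in seq_len(n_boot)) {
          boots[b, ] <- apply(m[sample.int(nrow(m), replace = TRUE), , drop = FALSE],
            2, median)
        }
        tibble(
          set = label, bin = bins, region = sub("_.*", "", bins),
          median = apply(m, 2, median),
          ci_lo = apply(boots, 2, quantile, 0.025),
          ci_hi = apply(boots, 2, quantile, 0.975),
          n = nrow(m)
        )
      })
  })
}

#' Region-resolved structure-contact counts, normalised and tested
#'
#' Per transcript and region: the track count sum divided by region length
#' in kilobases and by expression (TPM); group vs background compared by a
#' two-sided Welch t-test per region. Zero-length regions are excluded.
#'
#' @param transcripts Transcript tibble.
#' @param tracks Raw (unnormalised) track tibble.
#' @param group,background Gene id vectors.
#' @param track Track name (default `"paris_intra"`).
#' @param regions Regions to test.
#' @return A tibble `region`, `mean_group`, `mean_background`, `statistic`,
#'   `p_value`, `n_group`, `n_background`.
#' @export
paris_region_counts <- function(transcripts, tracks, group, background,
                                track = "paris_intra",
                                regions = c("utr5", "cds", "utr3")) {
  norm_counts <- function(ids, region) {
    rows <- transcripts[transcripts$gene_id %in% ids & !is.na(transcripts$utr5_len), ]
    vals <- purrr::map_dbl(seq_len(nrow(rows)), function(i) {
      rb <- region_bounds(rows[i, ], region)
      len <- rb[2] - rb[1]
      if (len == 0) return(NA_real_)
      v <- get_track(tracks, rows$gene_id[i], track)
      sum(v[(rb[1] + 1):rb[2]]) / (len / 1000) / rows$tpm[i]
    })
    vals[!is.na(vals)]
  }
  purrr::map_dfr(regions, function(reg) {
    g <- norm_counts(group, reg)
    b <- norm_counts(background, reg)
    tt <- welch_safe(g, b)
    tibble(
      region = reg, mean_group = mean(g), mean_background = mean(b),
      statistic = unname(tt$statistic), p_value = tt$p.value,
      n_group = length(g), n_background = length(b)
    )
  })
}

#' Expression- and length-normalised global occupancy comparison
#'
#' Per transcript: the track's total count scaled to counts-per-million over
#' the cohort, per kilobase of exonic length, divided by TPM. Group vs
#' background compared by a one-sided Wilcoxon rank-sum test
#' (group > background). Zero-TPM transcripts are excluded with a count.
#'
#' @param transcripts Transcript tibble.
#' @param tracks Raw track tibble.
#' @param group,background Gene id vectors.
#' @param track Track name (default `"iclip"`).
#' @return A list with `occupancy` (tibble `gene_id`, `set`, `occupancy`)
#'   and `test` (tibble `statistic`, `p_value`, `n_excluded`).
#' @export
global_occupancy <- function(transcripts, tracks, group, background,
                             track = "iclip") {
  ids <- c(group, background)
  rows <- transcripts[transcripts$gene_id %in% ids, ]
  totals <- purrr::map_dbl(rows$gene_id, function(g) sum(get_track(tracks, g, track)))
  lib_size <- sum(totals)
  excl <- rows$tpm <= 0
  occ <- (totals / lib_size * 1e6) / (rows$length / 1000) / ifelse(excl, NA, rows$tpm)
  df <- tibble(
    gene_id = rows$gene_id,
    set = ifelse(rows$gene_id %in% group, "group", "background"),
    occupancy = occ
  )
  keep <- df[!is.na(df$occupancy), ]
  wt <- suppressWarnings(wilcox.test(keep$occupancy[keep$set == "group"],
    keep$occupancy[keep$set == "background"], alternative = "greater"))
  list(
    occupancy = df,
    test = tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
      n_excluded = sum(excl))
  )
}
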