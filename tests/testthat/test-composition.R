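coding_tx <- function(gene_id, utr5, cds, utr3, tpm = 1, class = "negative") {
  tibble::tibble(
    gene_id = gene_id, biotype = "protein_coding", class = class,
    utr5_len = nchar(utr5), cds_len = nchar(cds), utr3_len = nchar(utr3),
    length = nchar(utr5) + nchar(cds) + nchar(utr3),
    sequence = paste0(utr5, cds, utr3), tpm = tpm
  )
}

test_that("binned nucleotide differences are exact for constructed groups", {
  g <- coding_tx("g1", strrep("C", 10), strrep("C", 30), strrep("C", 20))
  ctl <- coding_tx("c1", strrep("A", 10), strrep("A", 30), strrep("A", 20))
  tx <- dplyr::bind_rows(g, ctl)
  d <- binned_nucleotide_diff(tx, "g1", "c1", binning_scheme("by_region"))
  expect_equal(nrow(d), 110 * 4)
  expect_true(all(d$diff[d$nucleotide == "C"] == 1))
  expect_true(all(d$diff[d$nucleotide == "A"] == -1))
  expect_true(all(d$diff[d$nucleotide %in% c("G", "T")] == 0))
  # identical groups give all-zero differences
  d0 <- binned_nucleotide_diff(tx, "g1", "g1", binning_scheme("by_region"))
  expect_true(all(d0$diff == 0))
})

test_that("per-bin nucleotide differences sum to zero on random cohorts", {
  co <- fixture_cohort()
  pos <- co$tx$gene_id[co$tx$class == "positive"]
  neg <- co$tx$gene_id[co$tx$class == "negative"]
  d <- binned_nucleotide_diff(co$tx, pos, neg, binning_scheme("by_region"))
  sums <- d |>
    dplyr::group_by(bin) |>
    dplyr::summarise(s = sum(diff))
  expect_true(all(abs(sums$s) < 1e-12))
  # the planted C-rich CDS shows up
  expect_gt(mean(d$diff[d$region == "cds" & d$nucleotide == "C"]), 0.05)
  # whole-transcript scheme includes non-coding transcripts
  dw <- binned_nucleotide_diff(co$tx, pos, neg, binning_scheme("whole"))
  expect_equal(length(unique(dw$bin)), 100)
})

test_that("triplet frequencies use overlapping windows and conserve mass", {
  tx <- dplyr::bind_rows(
    coding_tx("g1", "", "CCCCCC", ""),
    coding_tx("c1", "", "ACACAC", "")
  )
  tf <- triplet_freq_diff(tx, "g1", "c1")
  expect_equal(tf$mean_group[tf$triplet == "CCC"], 1) # all 4 windows of CCCCCC
  expect_equal(sum(tf$mean_group), 1)
  expect_equal(sum(tf$mean_control), 1)
  tf0 <- triplet_freq_diff(tx, "g1", "g1")
  expect_true(all(tf0$diff == 0))
  expect_true(all(triplet_freqs_ok <- abs(tf$diff) <= 1))
  # U/T synonymy: same result with U-spelled input
  txu <- dplyr::mutate(tx, sequence = gsub("T", "U", sequence))
  expect_equal(triplet_freq_diff(txu, "g1", "c1"), tf)
  # planted CCC enrichment dominates the CDS triplet table of the cohort
  co <- fixture_cohort()
  pos <- co$tx$gene_id[co$tx$class == "positive"]
  neg <- co$tx$gene_id[co$tx$class == "negative"]
  tr <- triplet_freq_diff(co$tx, pos, neg, binning_scheme("by_region"))
  cds <- dplyr::filter(tr, region == "cds")
  expect_equal(cds$triplet[which.max(cds$diff)], "CCC")
})

test_that("binned medians and bootstrap CIs behave on constant and planted tracks", {
  tx <- dplyr::bind_rows(
    purrr::map(1:4, ~ coding_tx(paste0("g", .x), strrep("A", 20),
      strrep("A", 60), strrep("A", 40))),
    purrr::map(1:4, ~ coding_tx(paste0("c", .x), strrep("A", 20),
      strrep("A", 60), strrep("A", 40)))
  )
  tracks <- tidyr::expand_grid(gene_id = tx$gene_id, track = "iclip") |>
    dplyr::mutate(values = purrr::map(gene_id, ~ rep(3, 120)))
  med <- binned_signal_median(tx, tracks, "iclip", paste0("g", 1:4),
    paste0("c", 1:4), binning_scheme("by_region"), n_boot = 50, seed = 1)
  expect_true(all(med$median == 3))
  expect_true(all(med$ci_lo == 3 & med$ci_hi == 3))
  # CI always contains the median (percentile bootstrap property)
  co <- fixture_cohort()
  pos <- co$tx$gene_id[co$tx$class == "positive"]
  neg <- co$tx$gene_id[co$tx$class == "negative"]
  med2 <- binned_signal_median(co$tx, co$tracks_norm, "iclip", pos, neg,
    binning_scheme("by_region"), n_boot = 100, seed = 2)
  expect_true(all(med2$ci_lo <= med2$median + 1e-12))
  expect_true(all(med2$ci_hi >= med2$median - 1e-12))
  # planted 3'UTR enrichment: positive-group 3'UTR bins exceed CDS bins
  g <- dplyr::filter(med2, set == "group")
  expect_gt(mean(g$median[g$region == "utr3"]), mean(g$median[g$region == "cds"]))
  expect_error(binned_signal_median(tx, tracks, "iclip", "g1", paste0("c", 1:4),
    binning_scheme("by_region"), n_boot = 10, seed = 1), "fewer than 3")
})

test_that("region-resolved contact counts normalise by length and expression", {
  g <- coding_tx("g1", strrep("A", 100), strrep("A", 900), strrep("A", 100), tpm = 5)
  tracks <- tibble::tibble(gene_id = "g1", track = "paris_intra",
    values = list(c(rep(0, 100), rep(10 / 900, 900), rep(0, 100))))
  # CDS: total 10 counts over 0.9 kb at TPM 5 -> 10 / 0.9 / 5
  pr <- paris_region_counts(g, tracks, "g1", "g1", regions = "cds")
  expect_equal(pr$mean_group, 10 / 0.9 / 5)
  expect_equal(pr$mean_background, pr$mean_group)
  expect_equal(pr$statistic, 0)
  expect_equal(pr$p_value, 1)
  # planted CDS enrichment detected on the synthetic cohort
  co <- fixture_cohort()
  pos <- co$tx$gene_id[co$tx$class == "positive"]
  neg <- co$tx$gene_id[co$tx$class == "negative"]
  pr2 <- paris_region_counts(co$tx, co$tracks, pos, neg)
  cds <- dplyr::filter(pr2, region == "cds")
  expect_gt(cds$mean_group, cds$mean_background)
  expect_lt(cds$p_value, 0.01)
})

test_that("global occupancy is CPM-scale-invariant and detects planted shifts", {
  co <- fixture_cohort()
  pos <- co$tx$gene_id[co$tx$class == "positive"]
  neg <- co$tx$gene_id[co$tx$class == "negative"]
  occ <- global_occupancy(co$tx, co$tracks, pos, neg)
  expect_lt(occ$test$p_value, 0.01) # planted 3'UTR crosslink enrichment
  # doubling all raw counts leaves occupancies unchanged (CPM scaling)
  doubled <- dplyr::mutate(co$tracks,
    values = purrr::map(values, ~ .x * 2))
  occ2 <- global_occupancy(co$tx, doubled, pos, neg)
  expect_equal(occ$occupancy$occupancy, occ2$occupancy$occupancy)
  # identical groups: p near 0.5
  half <- neg[seq(1, length(neg), by = 2)]
  other <- neg[seq(2, length(neg), by = 2)]
  occ3 <- global_occupancy(co$tx, co$tracks, half, other)
  expect_gt(occ3$test$p_value, 0.05)
})

test_that("by_region and whole schemes agree for 10:50:50-proportioned transcripts", {
  tx <- dplyr::bind_rows(
    purrr::map(1:3, ~ coding_tx(paste0("g", .x), strrep("C", 10),
      strrep("C", 50), strrep("C", 50))),
    purrr::map(1:3, ~ coding_tx(paste0("c", .x), strrep("A", 10),
      strrep("A", 50), strrep("A", 50)))
  )
  dr <- binned_nucleotide_diff(tx, paste0("g", 1:3), paste0("c", 1:3),
    binning_scheme("by_region"))
  dw <- binned_nucleotide_diff(tx, paste0("g", 1:3), paste0("c", 1:3),
    binning_scheme("whole"))
  # with region lengths exactly 10/50/50 the 110 aligned single-position
  # bins coincide with 110-way proportional whole binning at 100 bins of
  # 1.1 positions; compare the C differences, which are constant here
  expect_true(all(dr$diff[dr$nucleotide == "C"] == 1))
  expect_true(all(dw$diff[dw$nucleotide == "C"] == 1))
})
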