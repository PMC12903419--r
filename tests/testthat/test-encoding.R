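test_that("genomic interval signal projects onto transcript coordinates", {
  tx <- tibble::tibble(
    gene_id = "g", chrom = "chr1", strand = "+",
    exon_starts = list(c(100L)), exon_ends = list(c(103L)), length = 3L
  )
  iv <- tibble::tibble(chrom = "chr1", start = 101L, end = 102L, score = 5)
  expect_equal(map_signal_to_transcript(tx[1, ], iv), c(0, 5, 0))
  # two exons concatenate 5'->3'
  tx2 <- tibble::tibble(
    gene_id = "g", chrom = "chr1", strand = "+",
    exon_starts = list(c(100L, 200L)), exon_ends = list(c(103L, 204L)),
    length = 7L
  )
  expect_equal(length(map_signal_to_transcript(tx2[1, ], iv)), 7)
  # interval spanning the intron contributes to each side; oracle is the
  # per-base genomic projection
  span <- tibble::tibble(chrom = "chr1", start = 102L, end = 202L, score = 2)
  got <- map_signal_to_transcript(tx2[1, ], span)
  oracle <- numeric(7)
  gpos <- c(100:102, 200:203) # transcript position -> genomic base
  for (p in seq_along(gpos)) {
    if (gpos[p] >= 102 && gpos[p] < 202) oracle[p] <- oracle[p] + 2
  }
  expect_equal(got, oracle)
  # intronic-only signal dropped silently
  intronic <- tibble::tibble(chrom = "chr1", start = 150L, end = 160L, score = 9)
  expect_equal(map_signal_to_transcript(tx2[1, ], intronic), numeric(7))
  # minus strand reverses to transcript orientation
  tx3 <- dplyr::mutate(tx, strand = "-")
  expect_equal(map_signal_to_transcript(tx3[1, ], iv), c(0, 5, 0))
})

test_that("expression normalisation divides count tracks only", {
  tx <- tibble::tibble(gene_id = "g", tpm = 5)
  tracks <- tibble::tibble(
    gene_id = "g", track = c("iclip", "rnafold", "postar3_X"),
    values = list(c(10, 0), c(1, 0), c(1, 1))
  )
  out <- normalize_tracks(tracks, tx)
  expect_equal(out$values[[1]], c(2, 0))
  expect_equal(out$values[[2]], c(1, 0))
  expect_equal(out$values[[3]], c(1, 1))
  expect_error(normalize_tracks(tracks, dplyr::mutate(tx, tpm = 0)), "zero TPM")
})

test_that("one-hot sequence encoding follows the A,C,G,T channel order", {
  expect_equal(encode_sequence("A")[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(unname(encode_sequence("ACGT")), diag(4))
  expect_equal(unname(encode_sequence("N")[, 1]), rep(0, 4))
  expect_equal(encode_sequence("ACGU"), encode_sequence("ACGT"))
  expect_error(encode_sequence("ACGX"), "invalid")
})

test_that("channel manifests are pure functions of subset and panel", {
  expect_equal(channel_manifest("iclip"), "iclip")
  full <- channel_manifest(
    c("sequence", "iclip", "m6a", "paris_intra", "paris_inter", "rnafold", "postar3"),
    rbp_panel = paste0("R", 1:46)
  )
  expect_equal(length(full), 56)
  expect_equal(full[1:4], paste0("seq_", c("A", "C", "G", "T")))
  expect_equal(full[56], "postar3_sum")
  expect_error(channel_manifest("nope"), "unknown")
})

test_that("assembled channels respect padding and canonical order", {
  co <- fixture_cohort()
  tx <- co$tx[1, ]
  l_max <- tx$length + 3L
  m <- assemble_channels(tx, co$tracks_norm,
    c("sequence", "iclip", "rnafold"), l_max)
  expect_equal(dim(m), c(6, l_max))
  expect_equal(rownames(m), c(paste0("seq_", c("A", "C", "G", "T")), "iclip", "rnafold"))
  expect_true(all(m[, (tx$length + 1):l_max] == -1))
  # round trip: one-hot channels recover the sequence
  onehot <- m[1:4, seq_len(tx$length)]
  rec <- paste(c("A", "C", "G", "T")[apply(onehot, 2, which.max)], collapse = "")
  expect_equal(rec, tx$sequence)
  # the summed panel channel equals the per-RBP sum
  rbps <- co$cfg$track_params$rbp_panel
  mp <- assemble_channels(tx, co$tracks_norm, "postar3", l_max, rbp_panel = rbps)
  expect_equal(unname(mp["postar3_sum", seq_len(tx$length)]),
    unname(colSums(mp[paste0("postar3_", rbps), seq_len(tx$length), drop = FALSE])))
})

test_that("encoded cohorts carry labels and channel subsetting preserves data", {
  co <- fixture_cohort()
  pos <- co$tx$gene_id[co$tx$class == "positive"][1:20]
  neg <- co$tx$gene_id[co$tx$class == "negative"][1:20]
  enc <- encode_dataset(co$tx, co$tracks_norm, pos, neg,
    datasets = c("sequence", "iclip", "rnafold"))
  expect_equal(dim(enc$x)[1], 6)
  expect_equal(sort(unique(as.character(enc$label))), c("negative", "positive"))
  sub <- subset_channels(enc, "iclip")
  expect_equal(dim(sub$x)[1], 1)
  expect_equal(sub$x[1, , ], enc$x[5, , ])
  expect_error(subset_channels(sub, "sequence"), "not in encoded")
})

test_that("the length baseline encodes only transcript length", {
  tx <- tibble::tibble(
    gene_id = c("a", "b", "c"), length = c(3L, 5L, 3L),
    sequence = c("AAA", "CCCCC", "GGG")
  )
  enc <- encode_length_baseline(tx, positive = c("a", "b"), negative = "c",
    l_max = 5L)
  expect_equal(enc$x[1, , 1], c(1, 1, 1, -1, -1))
  expect_equal(enc$x[1, , 1], enc$x[1, , 3]) # equal lengths, identical encoding
  expect_equal(dim(enc$x)[1], 1)
})

test_that("stratified split ratios hold and oversampling balances each subset", {
  labels <- factor(rep(c("positive", "negative"), each = 100))
  sp <- split_and_balance(labels, seed = 3)
  tab <- function(idx) table(labels[idx])
  expect_equal(as.vector(tab(sp$train)), c(70, 70))
  expect_equal(as.vector(tab(sp$validation)), c(15, 15))
  expect_equal(as.vector(tab(sp$test)), c(15, 15))
  # imbalanced input: minority oversampled to parity within each subset
  labs2 <- factor(c(rep("positive", 30), rep("negative", 70)))
  sp2 <- split_and_balance(labs2, seed = 4)
  t2 <- table(labs2[sp2$train_bal])
  expect_equal(unname(t2[["positive"]]), unname(t2[["negative"]]))
  expect_true(all(sp2$train %in% sp2$train_bal))
  expect_error(split_and_balance(factor(rep("positive", 5))), "2 classes")
})

test_that("splits are disjoint and exhaustive across seeds", {
  labels <- factor(rep(c("positive", "negative"), c(37, 63)))
  for (seed in 1:50) {
    sp <- split_and_balance(labels, seed = seed)
    all_idx <- c(sp$train, sp$validation, sp$test)
    expect_equal(sort(all_idx), seq_along(labels))
    expect_equal(anyDuplicated(all_idx), 0)
  }
})

test_that("representative transcript selection prefers expression then length", {
  tt <- tibble::tibble(
    gene_id = c("g1", "g1", "g1", "g2", "g2"),
    transcript_id = paste0("t", 1:5),
    length = c(100L, 300L, 200L, 50L, 80L),
    tpm_a = c(10, 10, 2, 5, 5), tpm_b = c(1, 1, 8, 2, 2)
  )
  sel <- select_representative_transcripts(tt, c("tpm_a", "tpm_b"))
  expect_equal(sel$transcript_id[sel$gene_id == "g1"], "t2") # tied max tpm, longer wins
  expect_equal(sel$transcript_id[sel$gene_id == "g2"], "t5")
})
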