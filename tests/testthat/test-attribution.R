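test_that("integrated gradients are exact for linear models", {
  withr::with_seed(5, {
    w <- matrix(rnorm(3 * 20), 3, 20)
    x <- matrix(rnorm(3 * 20), 3, 20)
    lm_mod <- linear_model(w)
    att <- integrated_gradients(lm_mod, x, steps = 8)
    expect_equal(att$channel, w * x, tolerance = 1e-15)
    expect_equal(att$position, colSums(w * x), tolerance = 1e-15)
    expect_equal(att$completeness$sum, att$completeness$delta_f, tolerance = 1e-15)
    # zero input = baseline gives identically zero attribution
    att0 <- integrated_gradients(lm_mod, matrix(0, 3, 20), steps = 8)
    expect_true(all(att0$channel == 0))
  })
})

test_that("integrated gradients satisfy completeness on a trained model", {
  toy <- toy_separable(n = 30, L = 260, shift = 1.5)
  sp <- split_and_balance(toy, seed = 1)
  m <- train_model(build_model(1, seed = 2), toy, sp,
    training_config(learning_rate = 2e-3, batch_size = 8L, max_epochs = 15L,
      seed = 3))
  expect_equal(m$val_auroc, 1)
  for (i in c(1, 15, 30)) {
    att <- integrated_gradients(m, toy$x[, , i], true_length = 260, steps = 256)
    rel <- abs(att$completeness$sum - att$completeness$delta_f) /
      max(abs(att$completeness$delta_f), 1e-8)
    expect_lt(rel, 0.01)
  }
  # x == baseline -> zero attribution
  att0 <- integrated_gradients(m, matrix(0, 1, 260), steps = 8)
  expect_true(all(abs(att0$channel) < 1e-12))
  expect_error(integrated_gradients(m, toy$x[, , 1], steps = 4), ">= 8")
})

test_that("binning is proportional, mean-preserving and rejects short transcripts", {
  const <- list(m1 = list(g1 = structure(
    list(position = rep(1, 200)), class = "smoops_attribution")))
  b <- bin_importance(const, n_bins = 100)
  expect_equal(unname(b[1, ]), rep(1, 100))
  ident <- list(m1 = list(g1 = structure(
    list(position = as.numeric(1:100)), class = "smoops_attribution")))
  expect_equal(unname(bin_importance(ident, n_bins = 100)[1, ]), as.numeric(1:100))
  # linear ramp over 1000 positions: each bin of 10 averages to its midpoint
  ramp <- list(m1 = list(g1 = structure(
    list(position = seq(0, 1, length.out = 1000)), class = "smoops_attribution")))
  br <- bin_importance(ramp, n_bins = 100)
  mids <- vapply(seq_len(100), function(k) {
    mean(seq(0, 1, length.out = 1000)[((k - 1) * 10 + 1):(k * 10)])
  }, numeric(1))
  expect_equal(unname(br[1, ]), mids, tolerance = 1e-9)
  short <- list(m1 = list(g1 = structure(
    list(position = rep(1, 50)), class = "smoops_attribution")))
  expect_error(bin_importance(short, n_bins = 100), "shorter")
  # two models stack in fixed order
  two <- list(
    mA = list(g1 = structure(list(position = rep(1, 100)), class = "smoops_attribution")),
    mB = list(g1 = structure(list(position = rep(2, 100)), class = "smoops_attribution"))
  )
  b2 <- bin_importance(two, n_bins = 100)
  expect_equal(unname(b2[1, ]), c(rep(1, 100), rep(2, 100)))
})

test_that("clustering recovers planted profile families across seeds", {
  for (seed in 1:5) {
    pp <- planted_profiles(30, seed = seed)
    cl <- cluster_profiles(pp$profiles, k = 2, seed = seed)
    agree <- max(
      mean(cl$assignment$cluster == pp$truth),
      mean(cl$assignment$cluster == 3 - pp$truth)
    )
    expect_gte(agree, 0.95)
    expect_equal(sort(unique(cl$assignment$cluster)), 1:2)
  }
})

test_that("clustering is invariant to row order and falls back for constant profiles", {
  pp <- planted_profiles(20, seed = 3)
  cl1 <- cluster_profiles(pp$profiles, k = 2)
  perm <- sample(nrow(pp$profiles))
  cl2 <- cluster_profiles(pp$profiles[perm, ], k = 2)
  j1 <- cl1$assignment$cluster[match(rownames(pp$profiles), cl1$assignment$gene_id)]
  j2 <- cl2$assignment$cluster[match(rownames(pp$profiles), cl2$assignment$gene_id)]
  expect_true(all(j1 == j2) || all(j1 == 3 - j2))
  withconst <- rbind(pp$profiles, tconst = rep(1, 100))
  expect_warning(cl3 <- cluster_profiles(withconst, k = 2), "constant")
  expect_equal(nrow(cl3$assignment), nrow(withconst))
  td <- tidy(cl3)
  expect_true(all(c("dim1", "dim2") %in% names(td)))
})

test_that("triplet importance slides a 3-window and keys by triplet identity", {
  att <- structure(list(position = c(0, 3, 6, 1, 2)), class = "smoops_attribution")
  ti <- triplet_importance(att, "ACGTA")
  expect_equal(nrow(ti), 3) # length reduced by two
  expect_equal(ti$score[1], 3) # mean of 0,3,6
  expect_equal(ti$triplet, c("ACG", "CGT", "GTA"))
  const <- structure(list(position = rep(2, 10)), class = "smoops_attribution")
  expect_true(all(triplet_importance(const, strrep("A", 10))$score == 2))
  expect_error(triplet_importance(
    structure(list(position = 1:2), class = "smoops_attribution"), "AC"), "shorter")
  # summary averages per segment and triplet
  atts <- list(g1 = structure(list(position = rep(1, 200)), class = "smoops_attribution"))
  seqs <- c(g1 = strrep("AC", 100))
  ts <- triplet_importance_summary(atts, seqs, n_segments = 10)
  expect_true(all(ts$score == 1))
  expect_true(all(ts$triplet %in% c("ACA", "CAC")))
})

test_that("RBP importance is zero for all-zero channels and ranks planted channels", {
  # attribution of an all-zero input channel is exactly zero (x - baseline = 0)
  withr::with_seed(8, {
    w <- matrix(rnorm(3 * 120), 3, 120)
    rownames(w) <- c("postar3_R1", "postar3_R2", "postar3_R3")
    atts <- purrr::map(1:20, function(i) {
      x <- matrix(abs(rnorm(3 * 120)), 3, 120,
        dimnames = list(rownames(w), NULL))
      x[2, ] <- 0 # R2 channel silent in every input
      x[1, ] <- x[1, ] * 3 # R1 channel carries most signal
      integrated_gradients(linear_model(abs(w)), x, steps = 8)
    })
    names(atts) <- paste0("g", 1:20)
    ri <- rbp_importance(atts, c("R1", "R2", "R3"))
    expect_equal(ri$mean_importance[ri$rbp == "R2"], 0)
    expect_equal(ri$rbp[which.max(ri$mean_importance)], "R1")
    expect_true(all(ri$ci_lo <= ri$mean_importance & ri$mean_importance <= ri$ci_hi))
    # CI width shrinks with the number of transcripts
    ri_small <- rbp_importance(atts[1:5], c("R1", "R2", "R3"))
    expect_lt(
      ri$ci_hi[ri$rbp == "R1"] - ri$ci_lo[ri$rbp == "R1"],
      ri_small$ci_hi[ri_small$rbp == "R1"] - ri_small$ci_lo[ri_small$rbp == "R1"]
    )
  })
})

test_that("region masking zeroes the region and degrades region-dependent signal", {
  co <- fixture_cohort()
  pos <- co$tx$gene_id[co$tx$class == "positive"]
  neg <- co$tx$gene_id[co$tx$class == "negative"]
  enc <- encode_dataset(co$tx, co$tracks_norm, pos, neg, datasets = "iclip")
  sp <- split_and_balance(enc, seed = 2)
  m <- train_model(build_model(1, seed = 4), enc, sp,
    training_config(batch_size = 8L, max_epochs = 6L, seed = 6))
  eval_idx <- c(sp$validation, sp$test)
  base <- evaluate_model(m, enc, eval_idx)
  masked <- purrr::map_dfr(c("utr5", "cds", "utr3"),
    ~ region_masking(m, enc, co$tx, .x, indices = eval_idx))
  # the planted signal is the 3'UTR crosslink enrichment: masking the 3'UTR
  # must hurt more than masking the 5'UTR
  expect_lt(masked$auroc[masked$region == "utr3"],
    masked$auroc[masked$region == "utr5"])
  expect_equal(masked$n_skipped, rep(sum(is.na(co$tx[match(enc$gene_id[eval_idx],
    co$tx$gene_id), ]$utr5_len)), 3))
  # masking a zero-length region changes nothing
  tx0 <- co$tx
  tx0$utr5_len[match(enc$gene_id, tx0$gene_id)] <- 0L
  same <- region_masking(m, enc, tx0, "utr5", indices = eval_idx)
  expect_equal(same$auroc, base$auroc)
})
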