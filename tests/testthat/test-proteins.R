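mk_tx <- function(gene_id, cds, class = "negative") {
  tibble::tibble(
    gene_id = gene_id, biotype = "protein_coding", class = class,
    utr5_len = 0L, cds_len = nchar(cds), utr3_len = 0L,
    length = nchar(cds), sequence = cds, tpm = 1
  )
}

test_that("translation follows the standard code with stop handling", {
  expect_equal(translate_cds(mk_tx("a", "ATGAAA"))$protein, "MK")
  expect_equal(translate_cds(mk_tx("b", "ATGTAA"))$protein, "M")
  expect_warning(
    tr <- translate_cds(mk_tx("c", "ATGTAAAAATAA")),
    "internal stop"
  )
  expect_equal(tr$protein, "M")
  # terminal stop removal: protein length = cds/3 - 1
  p <- translate_cds(mk_tx("d", "ATGGCCAAGTGA"))
  expect_equal(p$length, 12 / 3 - 1)
  # mass: residue monoisotopic masses + water (MK)
  expect_equal(p$protein, "MAK")
  expect_equal(translate_cds(mk_tx("a", "ATGAAA"))$mass,
    131.04049 + 128.09496 + 18.01056, tolerance = 1e-6)
})

test_that("amino-acid enrichment is exact on constructed groups and antisymmetric", {
  grp <- tibble::tibble(protein = c("SSSSKK", "SSSSRR")) # S at 4/6
  bgp <- tibble::tibble(protein = c("SSKKKK", "SSRRRR")) # S at 2/6
  aa <- aa_enrichment(grp, bgp)
  expect_equal(aa$log2fc[aa$aa == "S"], 1) # exactly 2x usage
  rev <- aa_enrichment(bgp, grp)
  expect_equal(rev$log2fc[rev$aa == "S"], -1) # antisymmetry under group swap
  ident <- aa_enrichment(grp, grp)
  expect_true(all(ident$log2fc[is.finite(ident$log2fc)] == 0))
  expect_true(all(ident$statistic[!is.na(ident$statistic)] == 0))
  # residue absent from the background mean -> undefined fold change
  expect_true(is.na(aa$log2fc[aa$aa == "W"]))
  expect_error(aa_enrichment(grp[0, ], bgp), "non-empty")
})

test_that("planted codon bias is recovered by amino-acid enrichment", {
  cfg <- sim_config(seed = 55, n_genes = 300, frac_noncoding = 0)
  tx <- generate_transcripts(cfg)
  prot <- generate_proteins(tx, cfg)
  aa <- aa_enrichment(prot[prot$class == "positive", ],
    prot[prot$class == "negative", ])
  # analytic expectation: per-residue usage from the codon model at the
  # configured per-nucleotide probabilities (stops excluded)
  expected_usage <- function(p) {
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)[gc != "*"]
    w <- vapply(codons, function(cod) {
      prod(p[strsplit(cod, "")[[1]]])
    }, numeric(1))
    tapply(w / sum(w), gc[codons], sum)
  }
  pos_p <- cfg$composition_params$positive$cds
  neg_p <- cfg$composition_params$negative$cds
  names(pos_p) <- names(neg_p) <- c("A", "C", "G", "T")
  lfc_exp <- log2(expected_usage(pos_p) / expected_usage(neg_p))
  planted <- names(sort(abs(lfc_exp), decreasing = TRUE))[1:6]
  top_obs <- aa$aa[order(abs(aa$log2fc), decreasing = TRUE)][1:6]
  expect_gte(length(intersect(top_obs, planted)) / 6, 0.9 - 1 / 6) # >= 5 of 6
  # proline (C-rich codons) must be enriched in the C-rich positive class
  expect_gt(aa$log2fc[aa$aa == "P"], 0.3)
  expect_lt(aa$p_value[aa$aa == "P"], 0.01)
})

test_that("planted serine enrichment reaches detection at moderate cohort size", {
  withr::with_seed(77, {
    base <- c(S = 0.10, A = 0.30, L = 0.30, K = 0.30)
    draw <- function(n, p) {
      vapply(seq_len(n), function(i) {
        paste(sample(names(p), 120, TRUE, prob = p), collapse = "")
      }, "")
    }
    grp <- tibble::tibble(protein = draw(150, c(S = 0.15, A = 0.2833,
      L = 0.2833, K = 0.2834)))
    bgp <- tibble::tibble(protein = draw(150, base))
    aa <- aa_enrichment(grp, bgp)
    expect_equal(aa$log2fc[aa$aa == "S"], log2(1.5), tolerance = 0.1)
    expect_lt(aa$p_value[aa$aa == "S"], 0.01)
  })
})

test_that("codon C/A content matches the genetic-code enumeration", {
  expect_equal(codon_ca_content("P", "C"), 9 / 12)
  expect_equal(codon_ca_content("K", "A"), 5 / 6)
  expect_equal(codon_ca_content("F", "C"), 1 / 6) # TTT, TTC
  expect_error(codon_ca_content("Z"), "unknown")
})

test_that("disorder statistics merge intervals and compare groups as specified", {
  g <- tibble::tibble(
    gene_id = "p1", length = 100L, mass = 1e4, protein = strrep("A", 100),
    idr_intervals = list(cbind(c(0L, 20L), c(30L, 50L)))
  )
  frac <- smoopr:::disorder_fraction(g$idr_intervals[[1]], 100)
  expect_equal(frac, 0.5) # [0,30) U [20,50) merges to [0,50)
  # merging is idempotent
  merged <- smoopr:::merge_intervals(g$idr_intervals[[1]])
  expect_equal(smoopr:::merge_intervals(merged), merged)
  none <- tibble::tibble(
    gene_id = "p2", length = 50L, mass = 5e3, protein = strrep("A", 50),
    idr_intervals = list(matrix(integer(), ncol = 2))
  )
  expect_equal(smoopr:::disorder_fraction(none$idr_intervals[[1]], 50), 0)
  ds <- disorder_stats(dplyr::bind_rows(g, g), dplyr::bind_rows(none, none))
  expect_equal(ds$summary$pct_with_idr, c(100, 0))
  expect_true(all(c("disorder_fraction", "mass") %in% ds$tests$quantity))
})

test_that("planted disorder differences are detected at moderate cohort size", {
  cfg <- sim_config(seed = 200, n_genes = 250, frac_noncoding = 0)
  tx <- generate_transcripts(cfg)
  prot <- generate_proteins(tx, cfg, idr_frac_positive = 0.5,
    idr_frac_negative = 0.2)
  ds <- disorder_stats(prot[prot$class == "positive", ],
    prot[prot$class == "negative", ])
  expect_lt(ds$tests$p_value[ds$tests$quantity == "disorder_fraction"], 0.01)
  expect_gt(ds$summary$mean_disorder_fraction[1],
    ds$summary$mean_disorder_fraction[2])
  # optional precomputed condensate scores flow through a Welch test
  prot$picnic_score <- ifelse(prot$class == "positive",
    rnorm(nrow(prot), 0.7, 0.1), rnorm(nrow(prot), 0.4, 0.1))
  ds2 <- disorder_stats(prot[prot$class == "positive", ],
    prot[prot$class == "negative", ])
  expect_true("picnic_score" %in% ds2$tests$quantity)
  expect_lt(ds2$tests$p_value[ds2$tests$quantity == "picnic_score"], 0.01)
})
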