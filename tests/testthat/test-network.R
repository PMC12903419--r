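test_that("network construction merges undirected duplicates and drops intra records", {
  rec <- tibble::tribble(
    ~gene_a, ~gene_b, ~count, ~kind,
    "A", "B", 2L, "inter",
    "B", "A", 3L, "inter",
    "A", "A", 4L, "intra",
    "B", "C", 1L, "inter",
    "A", "C", 1L, "inter"
  )
  g <- build_rri_network(rec)
  expect_equal(igraph::ecount(g), 3)
  w <- igraph::E(g)$weight[igraph::get_edge_ids(g, c("A", "B"))]
  expect_equal(w, 5)
  # biotype exclusion
  g2 <- build_rri_network(rec, exclude_biotypes = "rRNA",
    biotypes = c(A = "mRNA", B = "rRNA", C = "mRNA"))
  expect_equal(igraph::ecount(g2), 1)
  empty <- build_rri_network(rec[0, ])
  expect_equal(igraph::vcount(empty), 0)
})

test_that("connectivity metrics match hand-enumerated small graphs", {
  tri <- graph_from_adj(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3))
  m <- connectivity_metrics(tri)
  expect_equal(m$edge_density, 1)
  expect_equal(m$global_clustering, 1)
  expect_equal(m$lcc_size, 3)
  expect_equal(m$avg_path_length, 1)
  # path A-B-C: 3 pairs with distances 1, 1, 2
  path <- graph_from_adj(matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
  mp <- connectivity_metrics(path)
  expect_equal(mp$edge_density, 2 / 3)
  expect_equal(mp$global_clustering, 0)
  expect_equal(mp$avg_path_length, 4 / 3)
  # two disconnected edges on 4 nodes
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- adj[2, 1] <- adj[3, 4] <- adj[4, 3] <- 1
  md <- connectivity_metrics(graph_from_adj(adj))
  expect_equal(md$edge_density, 2 / 6)
  expect_equal(md$lcc_size, 2)
  expect_warning(connectivity_metrics(graph_from_adj(matrix(0, 1, 1))), "density")
})

test_that("metrics agree with the brute-force oracle on exhaustive and random graphs", {
  # all 64 graphs on 4 nodes
  for (code in 0:63) {
    bits <- as.integer(intToBits(code))[1:6]
    adj <- matrix(0, 4, 4)
    adj[upper.tri(adj)] <- bits
    adj <- adj + t(adj)
    got <- connectivity_metrics(graph_from_adj(adj))
    want <- metrics_oracle(adj)
    expect_equal(got$edge_density, want$edge_density)
    expect_equal(got$lcc_size, want$lcc_size)
    expect_equal(got$global_clustering, want$global_clustering)
    expect_equal(got$avg_path_length, want$avg_path_length)
  }
  # random graphs on 5-8 nodes
  withr::with_seed(99, {
    for (rep in 1:40) {
      n <- sample(5:8, 1)
      adj <- matrix(0, n, n)
      adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, runif(1, 0.2, 0.8))
      adj <- adj + t(adj)
      got <- connectivity_metrics(graph_from_adj(adj))
      want <- metrics_oracle(adj)
      expect_equal(got$edge_density, want$edge_density)
      expect_equal(got$lcc_size, want$lcc_size)
      expect_equal(got$global_clustering, want$global_clustering)
      expect_equal(got$avg_path_length, want$avg_path_length)
    }
  })
})

test_that("degree-matched sampling respects tolerance, distinctness and feasibility", {
  co <- fixture_cohort()
  cfg <- co$cfg
  hy <- generate_hybrids(co$tx, co$tx$gene_id[1:10], cfg)
  g <- build_rri_network(hy)
  deg <- igraph::degree(g)
  targets <- unname(sample(deg, 12))
  withr::with_seed(3, {
    for (rep in 1:200) {
      s <- degree_matched_sample(g, targets, tolerance = 1)
      expect_equal(length(s), length(targets))
      expect_false(anyDuplicated(s) > 0)
      expect_true(all(abs(deg[s] - targets) <= 1))
    }
  })
  expect_error(degree_matched_sample(g, max(deg) + 10, tolerance = 1),
    class = "smoopr_infeasible_matching")
})

test_that("degree-matched sampling is uniform over eligible nodes on a regular toy", {
  # 5-cycle: all degrees 2, one target of degree 2 -> uniform over 5 nodes
  g <- igraph::make_ring(5)
  igraph::V(g)$name <- paste0("n", 1:5)
  withr::with_seed(11, {
    picks <- replicate(2000, degree_matched_sample(g, 2, tolerance = 0))
  })
  tab <- table(picks)
  expect_equal(length(tab), 5)
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("permutation test follows the add-one estimator and detects planted communities", {
  cfg <- sim_config(seed = 8, n_genes = 120)
  tx <- generate_transcripts(cfg)
  focal <- tx$gene_id[seq_len(15)]
  hy <- generate_hybrids(tx, focal, cfg)
  g <- build_rri_network(hy)
  pt <- permutation_test(g, focal, n_iter = 499, seed = 21)
  # the planted community (p = 0.25 vs background 0.02) beats every null
  expect_equal(pt$p_values[["edge_density"]], 1 / 500)
  expect_equal(nrow(pt$null_samples), 499)
  expect_true(all(pt$p_values > 0))
  expect_error(permutation_test(g, focal[1], n_iter = 10, seed = 1), "at least 2")
  td <- tidy(pt)
  expect_equal(nrow(td), 4)
  expect_equal(td$p_value[td$metric == "edge_density"], 1 / 500)
})

test_that("permutation p decreases as the planted edge probability grows", {
  ps <- purrr::map_dbl(c(0.02, 0.08, 0.25), function(pp) {
    cfg <- sim_config(seed = 33, n_genes = 100)
    cfg$network_params$p_planted <- pp
    tx <- generate_transcripts(cfg)
    focal <- tx$gene_id[1:15]
    g <- build_rri_network(generate_hybrids(tx, focal, cfg))
    permutation_test(g, focal, n_iter = 199, seed = 5,
      metrics = "edge_density")$p_values[["edge_density"]]
  })
  expect_true(all(diff(ps) <= 0))
  expect_lt(ps[3], ps[1])
})

test_that("random-graph comparison is forced for complete graphs and flags planted clustering", {
  comp <- igraph::make_full_graph(5)
  igraph::V(comp)$name <- paste0("n", 1:5)
  rc <- compare_to_random_graph(comp, n_random = 20, seed = 2)
  expect_equal(rc$observed, 1)
  expect_true(all(rc$null == 1)) # same n, m forces the complete graph
  expect_warning(rc0 <- compare_to_random_graph(
    igraph::make_empty_graph(3, directed = FALSE), n_random = 5, seed = 1),
    "degenerate")
  expect_equal(rc0$observed, 0)
  # planted community raises clustering above ER nulls
  cfg <- sim_config(seed = 13, n_genes = 100)
  tx <- generate_transcripts(cfg)
  g <- build_rri_network(generate_hybrids(tx, tx$gene_id[1:20], cfg))
  rc2 <- compare_to_random_graph(g, n_random = 100, seed = 3)
  expect_gt(rc2$quantile, 0.95)
})
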