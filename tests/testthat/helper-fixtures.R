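# Shared fixtures, built once per test run.

# Small cohort with all generators applied (120 genes keeps most tests fast).
fixture_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 421, n_genes = 120)
      tx <- generate_transcripts(cfg)
      tracks <- generate_feature_tracks(tx, cfg)
      cache <<- list(
        cfg = cfg, tx = tx, tracks = tracks,
        tracks_norm = normalize_tracks(tracks, tx),
        enr = generate_enrichment_table(tx, cfg)
      )
    }
    cache
  }
})

# Reduced architecture for fast classifier mechanics tests (the full
# architecture's parameter accounting has its own dedicated tests).
tiny_arch <- function(dropout = 0) {
  arch_config(
    conv_filters = c(4L, 6L), dilations = c(1L, 2L), kernel_size = 3L,
    pool_size = 2L, dropout = dropout, gru_units = 4L,
    dense_units = c(8L, 4L)
  )
}

# A one-channel separable toy cohort: class determined by the mean track
# value. Length >= 256 so the full architecture's pooling cascade is usable.
toy_separable <- function(n = 60, L = 280, shift = 1, seed = 7) {
  withr::with_seed(seed, {
    lab <- rep(c("negative", "positive"), each = n / 2)
    x <- array(0, c(1, L, n))
    for (i in seq_len(n)) {
      x[1, , i] <- rnorm(L, mean = if (lab[i] == "positive") shift else 0, sd = 1)
    }
    structure(
      list(x = x, label = factor(lab, levels = c("negative", "positive")),
        gene_id = sprintf("T%03d", seq_len(n)), true_length = rep(L, n),
        manifest = "toy", datasets = "toy"),
      class = "smoops_encoded"
    )
  })
}

# Brute-force connectivity oracle working directly on an adjacency matrix.
metrics_oracle <- function(adj) {
  n <- nrow(adj)
  m <- sum(adj[upper.tri(adj)])
  density <- if (n < 2) 0 else m / (n * (n - 1) / 2)
  # triangles and connected triples by enumeration
  tri <- 0
  triples <- 0
  if (n >= 3) {
    for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
      e <- adj[i, j] + adj[i, k] + adj[j, k]
      if (e == 3) tri <- tri + 1
    }
  }
  for (ctr in seq_len(n)) {
    d <- sum(adj[ctr, ])
    triples <- triples + d * (d - 1) / 2
  }
  clustering <- if (triples == 0) 0 else 3 * tri / triples
  # components via reachability closure
  reach <- adj > 0
  diag(reach) <- TRUE
  for (rep in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  comp <- rep(NA_integer_, n)
  cid <- 0
  for (i in seq_len(n)) {
    if (is.na(comp[i])) {
      cid <- cid + 1
      comp[reach[i, ]] <- cid
    }
  }
  lcc_nodes <- which(comp == which.max(tabulate(comp)))
  # Floyd-Warshall on the largest component
  avg_path <- NA_real_
  if (length(lcc_nodes) >= 2) {
    sub <- adj[lcc_nodes, lcc_nodes, drop = FALSE]
    k <- length(lcc_nodes)
    dist <- matrix(Inf, k, k)
    dist[sub > 0] <- 1
    diag(dist) <- 0
    for (via in seq_len(k)) for (i in seq_len(k)) for (j in seq_len(k)) {
      if (dist[i, via] + dist[via, j] < dist[i, j]) {
        dist[i, j] <- dist[i, via] + dist[via, j]
      }
    }
    avg_path <- mean(dist[upper.tri(dist)])
  }
  list(edge_density = density, lcc_size = length(lcc_nodes),
    global_clustering = clustering, avg_path_length = avg_path)
}

# igraph from an adjacency matrix with letter names.
graph_from_adj <- function(adj) {
  rownames(adj) <- colnames(adj) <- paste0("n", seq_len(nrow(adj)))
  igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
}

# Exhaustive hypergeometric upper-tail oracle: enumerate all draws of size
# |smoops| from the background and count overlaps >= observed.
hyper_oracle <- function(background, granule, smoops_size, observed) {
  draws <- combn(background, smoops_size, simplify = FALSE)
  mean(vapply(draws, function(d) sum(d %in% granule) >= observed, logical(1)))
}

# Closed-form trainable-parameter count for the fixed architecture,
# written independently of the builder: per-block conv kernels and biases
# plus normalisation pairs, reset-after recurrent parameters with two bias
# sets per direction, dense head with normalisation, softmax output.
param_oracle <- function(C) {
  filters <- c(108, 144, 192, 256)
  total <- 0
  cin <- C
  for (f in filters) {
    total <- total + (9 * cin * f + f) + 2 * f
    cin <- f
  }
  u <- 128
  per_dir <- 3 * u * cin + 3 * u * u + 6 * u
  total <- total + 2 * per_dir + 2 * (2 * u)
  total <- total + (2 * u * 64 + 64) + 2 * 64
  total <- total + (64 * 32 + 32) + 2 * 32
  total <- total + (32 * 2 + 2)
  total
}

# Two planted profile families: a 3'-skewed ramp and a 5'-peaked decay.
planted_profiles <- function(n_per, seed, noise = 0.3) {
  withr::with_seed(seed, {
    shapes <- list(
      function() seq(0, 1, length.out = 100) + rnorm(100, 0, noise),
      function() exp(-seq(0, 5, length.out = 100)) + rnorm(100, 0, noise)
    )
    m <- do.call(rbind, purrr::map(rep(1:2, each = n_per), ~ shapes[[.x]]()))
    rownames(m) <- sprintf("t%03d", seq_len(2 * n_per))
    list(profiles = m, truth = rep(1:2, each = n_per))
  })
}

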