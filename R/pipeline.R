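#' Demo pipeline configuration
#'
#' Desk-scale defaults wiring every module together: a 400-gene synthetic
#' cohort, three data layers (sequence, crosslinks, predicted pairedness —
#' the last carries no class signal and acts as the noise layer), powerset
#' training with 2 replicates, a seeded permutation network test and
#' integrated-gradients deconvolution.
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_genes Cohort size.
#' @param datasets Data layers for the powerset (subset of the encoder's
#'   datasets).
#' @param replicates Training replicates per subset.
#' @param batch_size,max_epochs Training scale.
#' @param n_iter_perm Permutation iterations for the network test.
#' @param focal_size Planted community size (drawn from called smOOPs).
#' @param ig_steps Integrated-gradients path points in the demo.
#' @param sim Optional [sim_config()] override (its seed is replaced by
#'   `seed`).
#' @return A list of class `smoops_demo_config`.
#' @export
demo_config <- function(seed = 1L, n_genes = 400L,
                        datasets = c("sequence", "iclip", "rnafold"),
                        replicates = 2L, batch_size = 8L, max_epochs = 8L,
                        n_iter_perm = 1999L, focal_size = 30L,
                        ig_steps = 8L, sim = NULL) {
  if (is.null(sim)) sim <- sim_config(seed = seed, n_genes = n_genes)
  sim$seed <- as.integer(seed)
  sim$n_genes <- as.integer(n_genes)
  structure(
    list(seed = as.integer(seed), datasets = datasets,
      replicates = as.integer(replicates), batch_size = as.integer(batch_size),
      max_epochs = as.integer(max_epochs), n_iter_perm = as.integer(n_iter_perm),
      focal_size = as.integer(focal_size), ig_steps = as.integer(ig_steps),
      sim = sim),
    class = "smoops_demo_config"
  )
}

#' Run the end-to-end synthetic demo pipeline
#'
#' Simulates a cohort with planted signal, calls smOOPs and common controls
#' from the enrichment table, tests granule overlap, builds the RNA-RNA
#' proximity network and tests the planted community against the
#' degree-matched null, encodes the feature layers, trains the powerset of
#' models, computes per-dataset AUROC improvements and pairwise overlap,
#' deconvolves the best single-dataset models with integrated gradients,
#' clusters the binned importance profiles, and validates composition,
#' crosslink and protein-level differences directly.
#'
#' @param config A [demo_config()].
#' @param verbose Print stage progress.
#' @return A list of class `smoops_demo_report` (JSON-serialisable via
#'   [write_demo_report()]).
#' @export
run_demo <- function(config = demo_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- Sys.time()
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("demo stage '%s' failed: %s (seed %d, %d genes)",
        name, conditionMessage(e), config$seed, config$sim$n_genes))
    })
  }
  report <- list(seed = config$seed, n_genes = config$sim$n_genes)

  say("simulating cohort (%d genes)...", config$sim$n_genes)
  sim <- config$sim
  tx <- stage("simulate", generate_transcripts(sim))
  tracks <- stage("simulate", generate_feature_tracks(tx, sim))
  tracks_norm <- stage("simulate", normalize_tracks(tracks, tx))
  enr <- stage("simulate", generate_enrichment_table(tx, sim))

  say("calling smOOPs and common controls...")
  calls <- stage("calling", {
    per_stage <- purrr::map(setNames(STAGES, STAGES), ~ call_smoops(enr, stage = .x))
    smoops <- sort(unique(unlist(per_stage)))
    controls <- call_common_controls(enr)
    truth <- setNames(tx$class, tx$gene_id)
    list(per_stage = per_stage, smoops = smoops, controls = controls,
      sensitivity = mean(tx$gene_id[tx$class == "positive"] %in% smoops),
      control_purity = if (length(controls)) mean(truth[controls] == "negative") else NA_real_)
  })
  report$calling <- list(
    n_smoops = length(calls$smoops),
    n_per_stage = purrr::map_int(calls$per_stage, length),
    n_controls = length(calls$controls),
    sensitivity = calls$sensitivity,
    control_purity = calls$control_purity,
    biotypes = biotype_breakdown(calls$smoops, tx)
  )

  say("granule overlap test...")
  report$granules <- stage("granules", with_seed(child_seed(config$seed, "granules"), {
    background <- tx$gene_id
    non_smoops <- setdiff(background, calls$smoops)
    overlapping <- c(
      sample(calls$smoops, min(40, length(calls$smoops))),
      sample(non_smoops, 40)
    )
    random_set <- sample(background, 80)
    granule_enrichment(calls$smoops,
      list(planted = overlapping, random = random_set), background)
  }))

  say("network permutation test (%d iterations)...", config$n_iter_perm)
  net <- stage("network", {
    focal <- with_seed(child_seed(config$seed, "focal"), {
      sample(calls$smoops, min(config$focal_size, length(calls$smoops)))
    })
    hybrids <- generate_hybrids(tx, focal, sim)
    graph <- build_rri_network(hybrids)
    pt <- permutation_test(graph, focal, n_iter = config$n_iter_perm,
      seed = child_seed(config$seed, "permtest"))
    rg <- compare_to_random_graph(graph, n_random = 100,
      seed = child_seed(config$seed, "gnm"))
    list(focal = focal, graph = graph, permtest = pt, random_graph = rg)
  })
  report$network <- list(
    n_nodes = igraph::vcount(net$graph), n_edges = igraph::ecount(net$graph),
    observed = net$permtest$observed,
    p_values = as.list(net$permtest$p_values),
    clustering_vs_random_quantile = net$random_graph$quantile
  )

  say("encoding %s...", paste(config$datasets, collapse = "+"))
  enc <- stage("encode", encode_dataset(tx, tracks_norm,
    positive = calls$smoops, negative = calls$controls,
    datasets = config$datasets))
  split <- stage("encode", split_and_balance(enc,
    seed = child_seed(config$seed, "split")))
  report$encoding <- list(
    n_examples = dim(enc$x)[3], n_channels = dim(enc$x)[1],
    l_max = dim(enc$x)[2],
    split_sizes = purrr::map_int(split[c("train", "validation", "test")], length)
  )

  say("powerset training (%d subsets x %d replicates)...",
    2^length(config$datasets) - 1, config$replicates)
  tcfg <- training_config(batch_size = config$batch_size,
    max_epochs = config$max_epochs, seed = child_seed(config$seed, "train"))
  runs <- stage("powerset", run_powerset(enc, split,
    datasets = config$datasets, replicates = config$replicates, cfg = tcfg))
  best <- best_per_subset(runs)
  attr(best, "datasets") <- config$datasets
  improvements <- purrr::map_dfr(config$datasets,
    ~ dataset_improvement(best, .x, config$datasets))
  pair <- utils::combn(config$datasets, 2, simplify = FALSE)
  overlaps <- purrr::map_dfr(pair, ~ pairwise_overlap(best, .x[1], .x[2], config$datasets))
  report$powerset <- list(
    runs = dplyr::select(runs, -dplyr::any_of("deltas")),
    best = dplyr::select(best, "subset", "auroc", "accuracy"),
    best_auroc = max(best$auroc),
    improvements = dplyr::select(improvements, -"deltas"),
    pairwise_overlap = dplyr::select(overlaps, -"deltas")
  )

  say("integrated-gradients deconvolution...")
  deconv <- stage("attribution", {
    # attribute the called smOOPs (profiles need >= 100 positions to bin)
    eval_idx <- which(enc$label == "positive" & enc$true_length >= 100)
    # the strongest single-dataset models drive the deconvolution
    single_auc <- setNames(best$auroc[match(config$datasets, best$subset)], config$datasets)
    top_models <- names(sort(single_auc, decreasing = TRUE))[seq_len(min(2, length(single_auc)))]
    profiles <- purrr::map(setNames(top_models, top_models), function(d) {
      e <- subset_channels(enc, d)
      si <- which(purrr::map_lgl(enumerate_subsets(config$datasets),
        ~ identical(subset_key(.x, config$datasets), d)))
      rbest <- best$replicate[best$subset == d]
      seed_r <- tcfg$seed + 1000L * si + rbest
      m <- build_model(dim(e$x)[1], seed = seed_r)
      rcfg <- tcfg; rcfg$seed <- seed_r
      m <- train_model(m, e, split, rcfg)
      attribute_cohort(m, e, eval_idx, steps = config$ig_steps)
    })
    binned <- bin_importance(profiles, n_bins = 100)
    clusters <- cluster_profiles(binned, k = 2,
      seed = child_seed(config$seed, "cluster"))
    list(models = top_models, binned = binned, clusters = clusters)
  })
  report$deconvolution <- list(
    models = deconv$models,
    cluster_sizes = as.list(table(deconv$clusters$assignment$cluster))
  )

  say("composition and signal validation...")
  report$composition <- stage("composition", {
    nt <- binned_nucleotide_diff(tx, calls$smoops, calls$controls,
      binning_scheme("by_region"))
    tri <- triplet_freq_diff(tx, calls$smoops, calls$controls,
      binning_scheme("by_region"))
    cds_tri <- dplyr::arrange(dplyr::filter(tri, .data$region == "cds"),
      dplyr::desc(.data$diff))
    med <- binned_signal_median(tx, tracks_norm, "iclip", calls$smoops,
      calls$controls, binning_scheme("by_region"), n_boot = 200,
      seed = child_seed(config$seed, "boot"))
    paris <- paris_region_counts(tx, tracks, calls$smoops, calls$controls)
    occ <- global_occupancy(tx, tracks, calls$smoops, calls$controls)
    list(
      mean_cds_c_diff = mean(nt$diff[nt$region == "cds" & nt$nucleotide == "C"]),
      top_cds_triplets = head(cds_tri$triplet, 5),
      utr3_vs_cds_median_ratio = {
        g <- med[med$set == "group", ]
        mean(g$median[g$region == "utr3"]) / max(mean(g$median[g$region == "cds"]), 1e-12)
      },
      paris = paris,
      occupancy_p = occ$test$p_value
    )
  })

  say("protein features...")
  report$proteins <- stage("proteins", {
    prot <- generate_proteins(tx, sim)
    grp <- prot[prot$gene_id %in% calls$smoops, ]
    bgp <- prot[prot$gene_id %in% calls$controls, ]
    aa <- aa_enrichment(grp, bgp)
    ds <- disorder_stats(grp, bgp)
    list(
      aa_top = head(dplyr::arrange(aa, dplyr::desc(.data$log2fc)), 5),
      disorder = ds$summary, tests = ds$tests
    )
  })

  report$runtime_minutes <- as.numeric(Sys.time() - t_start, units = "mins")
  say("done in %.1f min", report$runtime_minutes)
  structure(report, class = "smoops_demo_report")
}

#' Serialise a demo report to JSON
#'
#' @param report A `smoops_demo_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_demo_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
    dataframe = "rows", force = TRUE)
  invisible(path)
}

#' @export
print.smoops_demo_report <- function(x, ...) {
  cat(sprintf("smOOPs demo report (seed %d, %d genes)\n", x$seed, x$n_genes))
  cat(sprintf("  smOOPs called: %d  controls: %d  (sensitivity %.2f)\n",
    x$calling$n_smoops, x$calling$n_controls, x$calling$sensitivity))
  cat(sprintf("  network edge-density permutation p: %.4g\n",
    x$network$p_values$edge_density))
  cat(sprintf("  best powerset AUROC: %.3f\n", x$powerset$best_auroc))
  cat(sprintf("  cluster sizes: %s\n",
    paste(unlist(x$deconvolution$cluster_sizes), collapse = "/")))
  cat(sprintf("  runtime: %.1f min\n", x$runtime_minutes))
  invisible(x)
}
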