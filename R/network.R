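#' Build a weighted RNA-RNA interaction graph from hybrid records
#'
#' Keeps intermolecular records only, drops genes with excluded biotypes
#' (e.g. rRNA/tRNA/mitochondrial annotations when present) and merges
#' duplicate pairs by summing hybrid counts. The result is an undirected
#' igraph with edge attribute `weight` (hybrid count); degree is the number
#' of distinct neighbours.
#'
#' @param records Tibble `gene_a`, `gene_b`, `count`, `kind`.
#' @param exclude_biotypes Character vector of biotypes to drop (requires
#'   `biotypes`).
#' @param biotypes Optional named character vector mapping gene id to biotype.
#' @return An [igraph::graph] object.
#' @export
build_rri_network <- function(records, exclude_biotypes = character(), biotypes = NULL) {
  edges <- dplyr::filter(records, .data$kind == "inter", .data$gene_a != .data$gene_b)
  if (length(exclude_biotypes)) {
    if (is.null(biotypes)) abort("`biotypes` needed when excluding biotypes")
    bad <- names(biotypes)[biotypes %in% exclude_biotypes]
    edges <- dplyr::filter(edges, !.data$gene_a %in% bad, !.data$gene_b %in% bad)
  }
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  edges <- edges |>
    dplyr::mutate(
      a = pmin(.data$gene_a, .data$gene_b),
      b = pmax(.data$gene_a, .data$gene_b)
    ) |>
    dplyr::group_by(.data$a, .data$b) |>
    dplyr::summarise(weight = sum(.data$count), .groups = "drop")
  igraph::graph_from_data_frame(edges, directed = FALSE)
}

#' Connectivity metrics of a graph or induced subgraph
#'
#' Edge density `m / (n(n-1)/2)`, size of the largest connected component,
#' global clustering coefficient (transitivity: 3 x triangles / connected
#' triples) and the mean shortest-path length over node pairs within the
#' largest component. Metrics are computed on the unweighted topology.
#'
#' @param graph An igraph object.
#' @param node_subset Optional character vector of node names; metrics are
#'   then computed on the induced subgraph (nodes absent from the graph are
#'   ignored).
#' @param metrics Which metrics to compute.
#' @return A one-row tibble with the requested metrics.
#' @export
connectivity_metrics <- function(graph, node_subset = NULL,
                                 metrics = c("edge_density", "lcc_size",
                                   "global_clustering", "avg_path_length")) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!is.null(node_subset)) {
    keep <- intersect(node_subset, igraph::V(graph)$name)
    graph <- igraph::induced_subgraph(graph, keep)
  }
  n <- igraph::vcount(graph)
  out <- list()
  if ("edge_density" %in% metrics) {
    if (n < 2) {
      warn("edge density undefined for fewer than 2 nodes; reporting 0")
      out$edge_density <- 0
    } else {
      out$edge_density <- igraph::ecount(graph) / (n * (n - 1) / 2)
    }
  }
  comp <- NULL
  if (any(c("lcc_size", "avg_path_length") %in% metrics)) {
    comp <- igraph::components(graph)
  }
  if ("lcc_size" %in% metrics) {
    out$lcc_size <- if (n == 0) 0L else max(comp$csize)
  }
  if ("global_clustering" %in% metrics) {
    tr <- igraph::transitivity(graph, type = "global")
    out$global_clustering <- if (is.nan(tr)) 0 else tr
  }
  if ("avg_path_length" %in% metrics) {
    if (n == 0 || max(comp$csize) < 2) {
      out$avg_path_length <- NA_real_
    } else {
      lcc <- igraph::induced_subgraph(graph,
        which(comp$membership == which.max(comp$csize)))
      out$avg_path_length <- igraph::mean_distance(lcc, directed = FALSE)
    }
  }
  tibble::as_tibble(out)
}

#' Sample a degree-matched node set
#'
#' Draws one distinct node per target degree, each with degree within
#' `tolerance` of its target, uniformly among the eligible unused nodes.
#' Targets are processed in random order with restarts; an infeasible degree
#' raises an error naming it.
#'
#' @param graph An igraph object.
#' @param target_degrees Integer vector of target degrees.
#' @param tolerance Allowed absolute degree deviation (default 1).
#' @param max_restarts Greedy restarts before giving up.
#' @return A character vector of node names, one per target degree.
#' @export
degree_matched_sample <- function(graph, target_degrees, tolerance = 1,
                                  max_restarts = 20) {
  deg <- igraph::degree(graph)
  nodes <- names(deg)
  if (is.null(nodes)) nodes <- as.character(seq_along(deg))
  for (restart in seq_len(max_restarts)) {
    ord <- sample.int(length(target_degrees))
    used <- logical(length(deg))
    pick <- character(length(target_degrees))
    ok <- TRUE
    for (j in ord) {
      d <- target_degrees[j]
      elig <- which(!used & abs(deg - d) <= tolerance)
      if (length(elig) == 0) {
        ok <- FALSE
        failed_degree <- d
        break
      }
      sel <- if (length(elig) == 1) elig else elig[sample.int(length(elig), 1L)]
      used[sel] <- TRUE
      pick[j] <- nodes[sel]
    }
    if (ok) return(pick)
    # check plain infeasibility (ignoring the without-replacement constraint)
    if (!any(abs(deg - failed_degree) <= tolerance)) {
      abort(sprintf("no node with degree within %d of target degree %d",
        tolerance, failed_degree), class = "smoopr_infeasible_matching")
    }
  }
  abort(sprintf(
    "degree-matched sampling failed after %d restarts (unmatched degree %d)",
    max_restarts, failed_degree), class = "smoopr_infeasible_matching")
}

#' Permutation test of focal-set connectivity against a degree-matched null
#'
#' Computes connectivity metrics on the focal induced subgraph and compares
#' them with `n_iter` degree-matched random node sets of the same size and
#' (within `tolerance`) degree sequence. The one-sided p value per metric is
#' the add-one estimator `(1 + #\{null >= observed\}) / (1 + n_iter)`, which
#' can never be zero. For `avg_path_length`, where smaller values indicate
#' tighter connectivity, `alternative = "less"` counts `null <= observed`
#' instead.
#'
#' @param graph An igraph object with named nodes.
#' @param focal_set Character vector of focal node names (>= 2 present in the
#'   graph).
#' @param n_iter Number of null iterations (default 10000).
#' @param tolerance Degree-matching tolerance (default 1).
#' @param seed Integer seed.
#' @param metrics Metrics to test (see [connectivity_metrics()]).
#' @param alternative `"greater"` (default; observed >= null counts against
#'   the null) or `"less"`, applied to every requested metric.
#' @return An object of class `smoops_permtest`: list with `observed`
#'   (tibble), `null_samples` (tibble, one row per iteration), `p_values`
#'   (named numeric), `n_iter`, `degree_tolerance`.
#' @export
permutation_test <- function(graph, focal_set, n_iter = 10000, tolerance = 1,
                             seed = 1L,
                             metrics = c("edge_density", "lcc_size",
                               "global_clustering", "avg_path_length"),
                             alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  metrics <- match.arg(metrics, several.ok = TRUE)
  focal <- intersect(focal_set, igraph::V(graph)$name)
  if (length(focal) < 2) abort("`focal_set` must contain at least 2 graph nodes")
  observed <- connectivity_metrics(graph, focal, metrics = metrics)
  targets <- unname(igraph::degree(graph)[focal])
  null_samples <- with_seed(seed, {
    purrr::map_dfr(seq_len(n_iter), function(i) {
      nodes <- degree_matched_sample(graph, targets, tolerance = tolerance)
      connectivity_metrics(graph, nodes, metrics = metrics)
    })
  })
  p <- vapply(metrics, function(m) {
    nulls <- null_samples[[m]]
    obs <- observed[[m]]
    cmp <- if (alternative == "greater") nulls >= obs else nulls <= obs
    (1 + sum(cmp, na.rm = TRUE)) / (1 + n_iter)
  }, numeric(1))
  structure(
    list(observed = observed, null_samples = null_samples,
      p_values = p, n_iter = n_iter, degree_tolerance = tolerance,
      alternative = alternative, focal_size = length(focal)),
    class = "smoops_permtest"
  )
}

#' @export
print.smoops_permtest <- function(x, ...) {
  cat(sprintf(
    "Degree-matched permutation test (%d focal nodes, %d iterations, +/-%d degrees)\n",
    x$focal_size, x$n_iter, x$degree_tolerance))
  for (m in names(x$p_values)) {
    cat(sprintf("  %-18s observed %.4g   p = %.4g\n", m, x$observed[[m]], x$p_values[m]))
  }
  invisible(x)
}

#' Compare observed clustering with Erdos-Renyi random graphs
#'
#' Generates random graphs with the same node and edge counts and reports the
#' observed global clustering coefficient against the null distribution.
#'
#' @param graph An igraph object (>= 3 nodes for a meaningful comparison).
#' @param n_random Number of random graphs.
#' @param seed Integer seed.
#' @return A list with `observed`, `null` (numeric vector) and
#'   `quantile` (fraction of nulls below the observed value).
#' @export
compare_to_random_graph <- function(graph, n_random = 100, seed = 1L) {
  n <- igraph::vcount(graph)
  m <- igraph::ecount(graph)
  obs <- igraph::transitivity(graph, type = "global")
  if (is.nan(obs)) obs <- 0
  if (n == 0 || m == 0) {
    warn("degenerate graph: clustering comparison is uninformative")
    return(list(observed = obs, null = rep(0, n_random), quantile = NA_real_))
  }
  nulls <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      tr <- igraph::transitivity(igraph::sample_gnm(n, m), type = "global")
      if (is.nan(tr)) 0 else tr
    }, numeric(1))
  })
  list(observed = obs, null = nulls, quantile = mean(nulls < obs))
}
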