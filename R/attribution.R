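#' Integrated-gradients attribution for one encoded example
#'
#' Attribution of the positive-class softmax output, integrated along the
#' straight path from an all-zeros baseline to the input: the input minus
#' baseline times the path-averaged gradient, Riemann-approximated with
#' `steps` points. The quadrature is graded towards the baseline
#' (substituting alpha = u^2 with midpoints in u), because layer
#' normalisation makes the network's response change fastest where the
#' scaled input is near zero; a uniform grid under-samples that region.
#' For a linear map the approximation is exact for any number of steps;
#' completeness (attributions summing to the output difference from
#' baseline) improves with `steps` and is reported alongside the profile.
#'
#' @param model A trained `smoops_model` (dropout is disabled).
#' @param x A `channels x positions` input matrix (padded encoding).
#' @param true_length Positions beyond this are discarded from the profile.
#' @param steps Number of path integration points (>= 8).
#' @param baseline Baseline matrix (default all zeros).
#' @return An object of class `smoops_attribution`: list with `channel`
#'   (channels x true_length attribution matrix), `position` (per-nucleotide
#'   channel sums), `completeness` (list with `sum`, `delta_f`) and
#'   `manifest`.
#' @export
integrated_gradients <- function(model, x, true_length = ncol(x), steps = 64,
                                 baseline = NULL) {
  if (steps < 8) abort("`steps` must be >= 8")
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  C <- nrow(x); L <- ncol(x)
  if (inherits(model, "smoops_linear_model")) {
    if (is.null(baseline)) baseline <- matrix(0, C, L)
    diff <- x - baseline
    # the path-averaged gradient of a linear map is its (constant) weights
    channel <- (diff * model$w)[, seq_len(true_length), drop = FALSE]
    rownames(channel) <- rownames(x)
    return(structure(
      list(channel = channel, position = colSums(channel),
        completeness = list(sum = sum(diff * model$w),
          delta_f = sum(x * model$w) - sum(baseline * model$w)),
        manifest = rownames(x)),
      class = "smoops_attribution"
    ))
  }
  if (C != model$n_channels) {
    abort(sprintf("input has %d channels; model expects %d", C, model$n_channels))
  }
  if (is.null(baseline)) baseline <- matrix(0, C, L)
  diff <- x - baseline
  u <- (seq_len(steps) - 0.5) / steps
  alphas <- u^2
  weights <- 2 * u / steps # midpoint weights after the alpha = u^2 substitution
  X <- array(0, c(C, L, steps))
  for (s in seq_len(steps)) X[, , s] <- baseline + alphas[s] * diff
  fw <- model_forward(model, X, keep_cache = TRUE)
  probs <- fw$probs
  # d p_pos / d logits for each path point
  dlogits <- rbind(-probs[2, ] * probs[1, ], probs[2, ] * (1 - probs[2, ]))
  bw <- model_backward(model, fw$caches, dlogits,
    need_param_grads = FALSE, need_input_grad = TRUE)
  if (!all(is.finite(bw$dX))) abort("non-finite gradients in integrated gradients")
  wg <- bw$dX * rep(weights, each = C * L)
  avg_grad <- rowSums(wg, dims = 2)
  attr_full <- diff * avg_grad
  f_x <- model_forward(model, array(x, c(C, L, 1)))$probs[2, 1]
  f_b <- model_forward(model, array(baseline, c(C, L, 1)))$probs[2, 1]
  channel <- attr_full[, seq_len(true_length), drop = FALSE]
  rownames(channel) <- rownames(x)
  structure(
    list(
      channel = channel,
      position = colSums(channel),
      completeness = list(sum = sum(attr_full), delta_f = f_x - f_b),
      manifest = rownames(x)
    ),
    class = "smoops_attribution"
  )
}

#' A linear scoring model for attribution checks
#'
#' Output is the plain weighted sum `sum(w * x)`; integrated gradients on a
#' linear map equal `w * x` exactly for any number of path steps, which
#' makes this the reference case for verifying the attribution machinery.
#'
#' @param w Weight matrix (channels x positions).
#' @return An object of class `smoops_linear_model`.
#' @export
linear_model <- function(w) {
  structure(list(w = w), class = "smoops_linear_model")
}

#' Attribution profiles for a set of examples
#'
#' Runs [integrated_gradients()] for each selected example of an encoded
#' cohort.
#'
#' @param model A trained `smoops_model`.
#' @param encoded A `smoops_encoded` object (channels must match the model).
#' @param indices Which examples to attribute (default: all).
#' @param steps Path integration points.
#' @return A named list of `smoops_attribution` objects keyed by gene id.
#' @export
attribute_cohort <- function(model, encoded, indices = NULL, steps = 64) {
  if (is.null(indices)) indices <- seq_len(dim(encoded$x)[3])
  out <- purrr::map(indices, function(i) {
    integrated_gradients(model, encoded$x[, , i], encoded$true_length[i], steps)
  })
  names(out) <- encoded$gene_id[indices]
  out
}

# Proportional position -> bin assignment: position p (1-based) of L maps to
# bin floor((p-1) * n_bins / L) + 1; every position maps to exactly one bin
# and no bin is empty when L >= n_bins.
bin_of_positions <- function(L, n_bins) {
  floor((seq_len(L) - 1) * n_bins / L) + 1L
}

bin_vector <- function(v, n_bins) {
  b <- bin_of_positions(length(v), n_bins)
  as.numeric(tapply(v, b, mean))
}

#' Stack binned importance profiles across models
#'
#' Per model, partitions each transcript's per-nucleotide importance into
#' `n_bins` contiguous proportional bins (bin value = mean score) and stacks
#' the per-model bin vectors in fixed model order into one profile per
#' transcript.
#'
#' @param profiles A named list (model name -> named list of
#'   `smoops_attribution` keyed by gene id, as from [attribute_cohort()]).
#' @param n_bins Number of bins (default 100).
#' @return A matrix `transcripts x (models * n_bins)` with gene ids as
#'   rownames; attribute `models` records the stacking order.
#' @export
bin_importance <- function(profiles, n_bins = 100) {
  model_names <- names(profiles)
  if (is.null(model_names)) abort("`profiles` must be a named list of models")
  genes <- Reduce(intersect, purrr::map(profiles, names))
  if (length(genes) == 0) abort("no transcript present in all models' profiles")
  rows <- purrr::map(genes, function(g) {
    unlist(purrr::map(model_names, function(mn) {
      v <- profiles[[mn]][[g]]$position
      if (length(v) < n_bins) {
        abort(sprintf("transcript %s shorter than %d bins", g, n_bins))
      }
      bin_vector(v, n_bins)
    }))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- genes
  attr(m, "models") <- model_names
  attr(m, "n_bins") <- n_bins
  m
}

#' Cluster binned importance profiles into two groups
#'
#' Agglomerative (Ward) clustering on the correlation distance between
#' binned profiles, with a 2-D principal-coordinates embedding of the same
#' distance for visualisation. Cluster labels are ordered by decreasing
#' size. Transcripts with constant profiles (undefined correlation) are
#' assigned to the nearest cluster centroid (Euclidean) with a warning.
#'
#' @param binned Matrix from [bin_importance()].
#' @param k Number of clusters (default 2).
#' @param seed Integer seed (tie-breaking in the fallback assignment).
#' @return A list of class `smoops_clusters`: `assignment` tibble
#'   (`gene_id`, `cluster`), `embedding` (n x 2 matrix), `k`.
#' @export
cluster_profiles <- function(binned, k = 2, seed = 1L) {
  if (nrow(binned) < 2 * k) abort("need at least 2k profiles to cluster")
  sds <- apply(binned, 1, sd)
  degen <- sds == 0
  work <- binned[!degen, , drop = FALSE]
  if (nrow(work) < 2 * k) abort("too many degenerate (constant) profiles")
  cd <- 1 - cor(t(work))
  d <- as.dist(cd)
  hc <- hclust(d, method = "ward.D2")
  cl <- cutree(hc, k = k)
  # relabel by decreasing cluster size (ties: lower original label first)
  sizes <- table(cl)
  relabel <- setNames(rank(-as.numeric(sizes), ties.method = "first"), names(sizes))
  cl <- as.integer(relabel[as.character(cl)])
  emb <- cmdscale(d, k = 2)
  if (any(degen)) {
    warn(sprintf("%d constant profile(s) assigned by nearest centroid", sum(degen)))
    cents <- purrr::map(seq_len(k), function(ki) {
      colMeans(work[cl == ki, , drop = FALSE])
    })
    extra <- with_seed(seed, {
      vapply(which(degen), function(i) {
        dists <- vapply(cents, function(ce) sum((binned[i, ] - ce)^2), numeric(1))
        which.min(dists)
      }, integer(1))
    })
    assignment <- tibble(
      gene_id = c(rownames(work), rownames(binned)[degen]),
      cluster = c(cl, as.integer(extra))
    )
    emb_all <- matrix(0, nrow(binned), 2,
      dimnames = list(c(rownames(work), rownames(binned)[degen]), NULL))
    emb_all[seq_len(nrow(work)), ] <- emb
    emb <- emb_all
  } else {
    assignment <- tibble(gene_id = rownames(work), cluster = cl)
  }
  assignment <- assignment[match(rownames(binned), assignment$gene_id), ]
  structure(
    list(assignment = assignment, embedding = emb, k = k),
    class = "smoops_clusters"
  )
}

#' Sliding-window triplet importance
#'
#' Mean attribution over each 3-nucleotide window (stride 1), reducing the
#' transcript length by two, keyed by the triplet identity at that window.
#'
#' @param attribution A `smoops_attribution` (needs per-position scores).
#' @param sequence The transcript's nucleotide sequence (same length).
#' @return A tibble `pos`, `triplet`, `score` with `length - 2` rows.
#' @export
triplet_importance <- function(attribution, sequence) {
  v <- attribution$position
  L <- length(v)
  if (L < 3) abort("transcript shorter than 3 nucleotides")
  seqc <- gsub("U", "T", toupper(sequence))
  if (nchar(seqc) != L) abort("sequence length does not match attribution length")
  score <- (v[1:(L - 2)] + v[2:(L - 1)] + v[3:L]) / 3
  tibble(
    pos = seq_len(L - 2),
    triplet = substring(seqc, 1:(L - 2), 3:L),
    score = score
  )
}

#' Average triplet importance across transcripts in length-standardised segments
#'
#' Per transcript, triplet scores are assigned to `n_segments` proportional
#' segments; scores are then averaged per (segment, triplet) across all
#' transcripts.
#'
#' @param attributions Named list of `smoops_attribution` keyed by gene id.
#' @param sequences Named character vector of sequences.
#' @param n_segments Number of segments (default 100).
#' @return A tibble `segment`, `triplet`, `score`, `n`.
#' @export
triplet_importance_summary <- function(attributions, sequences, n_segments = 100) {
  rows <- purrr::imap_dfr(attributions, function(att, g) {
    ti <- triplet_importance(att, sequences[[g]])
    ti$segment <- bin_of_positions(nrow(ti), n_segments)
    ti
  })
  rows |>
    dplyr::group_by(.data$segment, .data$triplet) |>
    dplyr::summarise(score = mean(.data$score), n = dplyr::n(), .groups = "drop")
}

#' Per-RBP mean importance with normal-approximation 95 percent CI
#'
#' Averages the per-channel attribution of each RBP peak channel over all
#' positions and transcripts; the CI is mean +/- 1.96 standard errors over
#' transcripts.
#'
#' @param attributions Named list of `smoops_attribution` from a model that
#'   includes the RBP panel channels.
#' @param rbp_panel Panel RBP names.
#' @return A tibble `rbp`, `mean_importance`, `ci_lo`, `ci_hi`, `n`.
#' @export
rbp_importance <- function(attributions, rbp_panel) {
  purrr::map_dfr(rbp_panel, function(rbp) {
    ch <- paste0("postar3_", rbp)
    per_tx <- vapply(attributions, function(att) {
      if (!ch %in% att$manifest) {
        abort(sprintf("channel %s absent from attribution", ch))
      }
      mean(att$channel[ch, ])
    }, numeric(1))
    n <- length(per_tx)
    se <- sd(per_tx) / sqrt(n)
    tibble(
      rbp = rbp, mean_importance = mean(per_tx),
      ci_lo = mean(per_tx) - qnorm(0.975) * se,
      ci_hi = mean(per_tx) + qnorm(0.975) * se, n = n
    )
  })
}

#' Re-evaluate a model with one transcript region zeroed out
#'
#' Sets all channels to zero across the chosen region (5'UTR, CDS or 3'UTR)
#' of every coding transcript and reports the AUROC on the masked examples.
#' Transcripts lacking the region (non-coding) are skipped and counted.
#'
#' @param model A trained `smoops_model`.
#' @param encoded A `smoops_encoded` object.
#' @param transcripts The transcript tibble (region boundaries).
#' @param region One of `"utr5"`, `"cds"`, `"utr3"`.
#' @param indices Examples to use (default all).
#' @return A one-row tibble `region`, `auroc`, `accuracy`, `n`, `n_skipped`.
#' @export
region_masking <- function(model, encoded, transcripts,
                           region = c("utr5", "cds", "utr3"),
                           indices = NULL) {
  region <- match.arg(region)
  if (is.null(indices)) indices <- seq_len(dim(encoded$x)[3])
  tx <- transcripts[match(encoded$gene_id[indices], transcripts$gene_id), ]
  coding <- !is.na(tx$utr5_len)
  n_skipped <- sum(!coding)
  keep <- indices[coding]
  txk <- tx[coding, ]
  masked <- encoded$x[, , keep, drop = FALSE]
  for (j in seq_along(keep)) {
    rb <- region_bounds(txk[j, ], region)
    if (rb[2] > rb[1]) masked[, (rb[1] + 1):rb[2], j] <- 0
  }
  tmp <- encoded
  tmp$x <- masked
  tmp$label <- encoded$label[keep]
  tmp$gene_id <- encoded$gene_id[keep]
  tmp$true_length <- encoded$true_length[keep]
  ev <- evaluate_model(model, tmp)
  tibble(region = region, auroc = ev$auroc, accuracy = ev$accuracy,
    n = ev$n, n_skipped = n_skipped)
}
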