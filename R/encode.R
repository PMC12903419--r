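DATASET_NAMES <- c("sequence", "iclip", "m6a", "paris_intra", "paris_inter",
  "rnafold", "postar3")
NORMALIZED_TRACKS <- c("iclip", "m6a", "paris_intra", "paris_inter")

#' Project genomic interval signal onto transcript coordinates
#'
#' Initialises a zero vector per exon, adds interval scores at the positions
#' (0-based half-open genomic coordinates) overlapping each exon, and
#' concatenates exons 5' to 3' in transcript orientation. Signal outside all
#' exons (intronic) is silently dropped. Intervals spanning an exon boundary
#' contribute to each side separately.
#'
#' @param transcript A one-row transcript tibble (needs `chrom`, `strand`,
#'   `exon_starts`, `exon_ends`, `length`).
#' @param intervals Tibble `chrom`, `start`, `end`, `score` (0-based
#'   half-open).
#' @return A numeric vector of length `transcript$length`.
#' @export
map_signal_to_transcript <- function(transcript, intervals) {
  starts <- transcript$exon_starts[[1]]
  ends <- transcript$exon_ends[[1]]
  out <- numeric(transcript$length)
  iv <- dplyr::filter(intervals, .data$chrom == transcript$chrom)
  if (nrow(iv) > 0) {
    exon_r <- IRanges::IRanges(start = starts + 1L, end = ends)
    sig_r <- IRanges::IRanges(start = iv$start + 1L, end = iv$end)
    hits <- IRanges::findOverlaps(sig_r, exon_r)
    offsets <- cumsum(c(0L, ends - starts))
    for (h in seq_along(hits)) {
      i <- S4Vectors::queryHits(hits)[h]
      e <- S4Vectors::subjectHits(hits)[h]
      lo <- max(iv$start[i], starts[e])
      hi <- min(iv$end[i], ends[e])
      idx <- (offsets[e] + (lo - starts[e]) + 1L):(offsets[e] + (hi - starts[e]))
      out[idx] <- out[idx] + iv$score[i]
    }
  }
  if (transcript$strand == "-") out <- rev(out)
  out
}

#' Normalise count tracks to transcript expression
#'
#' Divides the count tracks (`iclip`, `m6a`, `paris_intra`, `paris_inter`) by
#' the transcript's TPM; binary tracks (`rnafold`, `postar3_*`) are left
#' untouched.
#'
#' @param tracks Track tibble from [generate_feature_tracks()].
#' @param transcripts Transcript tibble (for `tpm`).
#' @return The track tibble with normalised `values`.
#' @export
normalize_tracks <- function(tracks, transcripts) {
  tpm <- setNames(transcripts$tpm, transcripts$gene_id)
  bad <- transcripts$gene_id[transcripts$tpm <= 0]
  if (any(tracks$gene_id %in% bad)) {
    abort(sprintf("zero TPM for transcript(s): %s",
      paste(head(intersect(tracks$gene_id, bad), 3), collapse = ", ")))
  }
  tracks |>
    dplyr::mutate(values = purrr::pmap(list(.data$values, .data$track, .data$gene_id),
      function(v, tr, g) if (tr %in% NORMALIZED_TRACKS) v / tpm[[g]] else v))
}

#' One-hot encode a nucleotide sequence
#'
#' Channel order A, C, G, T (U is a synonym of T); N encodes as an all-zero
#' column; any other character is an error.
#'
#' @param sequence A nucleotide string.
#' @return A 4 x L numeric matrix with rownames `A`, `C`, `G`, `T`.
#' @export
#' @examples
#' encode_sequence("ACGT")
encode_sequence <- function(sequence) {
  chars <- strsplit(gsub("U", "T", toupper(sequence)), "")[[1]]
  bad <- setdiff(unique(chars), c("A", "C", "G", "T", "N"))
  if (length(bad)) abort(sprintf("invalid nucleotide(s): %s", paste(bad, collapse = ", ")))
  m <- matrix(0, nrow = 4, ncol = length(chars),
    dimnames = list(c("A", "C", "G", "T"), NULL))
  for (nt in c("A", "C", "G", "T")) m[nt, chars == nt] <- 1
  m
}

#' Channel manifest for a dataset subset
#'
#' The canonical channel order is: the 4 one-hot sequence channels (when
#' `sequence` is included), then `iclip`, `m6a`, `paris_intra`,
#' `paris_inter`, `rnafold` (one channel each, in that order, when
#' included), then one binary channel per panel RBP plus one summed
#' `postar3_sum` channel (when `postar3` is included). With all 7 datasets
#' and the full 46-RBP panel this yields 56 channels.
#'
#' @param datasets Character vector of dataset names (subset of
#'   `r paste(DATASET_NAMES, collapse = ", ")`).
#' @param rbp_panel Character vector of panel RBP names.
#' @param postar3_sum Include the summed panel channel (default TRUE).
#' @return Character vector of channel names.
#' @export
channel_manifest <- function(datasets, rbp_panel = character(),
                             postar3_sum = TRUE) {
  bad <- setdiff(datasets, DATASET_NAMES)
  if (length(bad)) abort(sprintf("unknown dataset(s): %s", paste(bad, collapse = ", ")))
  out <- character()
  if ("sequence" %in% datasets) out <- c(out, paste0("seq_", c("A", "C", "G", "T")))
  for (tr in c("iclip", "m6a", "paris_intra", "paris_inter", "rnafold")) {
    if (tr %in% datasets) out <- c(out, tr)
  }
  if ("postar3" %in% datasets) {
    out <- c(out, paste0("postar3_", rbp_panel))
    if (postar3_sum) out <- c(out, "postar3_sum")
  }
  out
}

#' Assemble the padded channel matrix for one transcript
#'
#' Stacks the requested data layers in the canonical channel order and pads
#' every channel with -1 beyond the transcript's true length up to `l_max`.
#'
#' @param transcript One-row transcript tibble.
#' @param tracks Track tibble (normalised; see [normalize_tracks()]).
#' @param datasets Dataset subset (see [channel_manifest()]).
#' @param l_max Padded length (>= transcript length).
#' @param rbp_panel Panel RBP names for `postar3`.
#' @param postar3_sum Include the summed panel channel.
#' @return A `channels x l_max` matrix with the manifest as rownames.
#' @export
assemble_channels <- function(transcript, tracks, datasets, l_max,
                              rbp_panel = character(), postar3_sum = TRUE) {
  manifest <- channel_manifest(datasets, rbp_panel, postar3_sum)
  L <- transcript$length
  if (L > l_max) abort(sprintf("transcript %s longer than l_max", transcript$gene_id))
  m <- matrix(-1, nrow = length(manifest), ncol = l_max,
    dimnames = list(manifest, NULL))
  fill <- matrix(0, nrow = length(manifest), ncol = L)
  rownames(fill) <- manifest
  if ("sequence" %in% datasets) {
    fill[paste0("seq_", c("A", "C", "G", "T")), ] <- encode_sequence(transcript$sequence)
  }
  for (tr in c("iclip", "m6a", "paris_intra", "paris_inter", "rnafold")) {
    if (tr %in% datasets) fill[tr, ] <- get_track(tracks, transcript$gene_id, tr)
  }
  if ("postar3" %in% datasets) {
    acc <- numeric(L)
    for (rbp in rbp_panel) {
      v <- get_track(tracks, transcript$gene_id, paste0("postar3_", rbp))
      fill[paste0("postar3_", rbp), ] <- v
      acc <- acc + v
    }
    if (postar3_sum) fill["postar3_sum", ] <- acc
  }
  if (L > 0) m[, seq_len(L)] <- fill
  m
}

#' Encode a cohort into a channels x positions x examples tensor
#'
#' Transcripts longer than `max_len` are excluded before encoding. Labels
#' come from the supplied positive/negative gene sets (e.g. called smOOPs
#' and common controls); genes in neither set are dropped.
#'
#' @param transcripts Transcript tibble.
#' @param tracks Normalised track tibble (may be NULL for sequence-only
#'   datasets).
#' @param positive,negative Character vectors of gene ids.
#' @param datasets Dataset subset.
#' @param rbp_panel Panel RBP names.
#' @param max_len Exclusion threshold on transcript length (default 20000).
#' @param l_max Padded length; defaults to the longest retained transcript.
#' @param postar3_sum Include the summed panel channel.
#' @return An object of class `smoops_encoded`: list with `x` (array
#'   channels x l_max x n), `label` (factor positive/negative), `gene_id`,
#'   `true_length`, `manifest`, `datasets`.
#' @export
encode_dataset <- function(transcripts, tracks, positive, negative,
                           datasets, rbp_panel = character(),
                           max_len = 20000, l_max = NULL,
                           postar3_sum = TRUE) {
  keep <- transcripts |>
    dplyr::filter(.data$gene_id %in% c(positive, negative), .data$length <= max_len)
  if (nrow(keep) == 0) abort("no transcripts to encode")
  if (is.null(l_max)) l_max <- max(keep$length)
  manifest <- channel_manifest(datasets, rbp_panel, postar3_sum)
  x <- array(0, dim = c(length(manifest), l_max, nrow(keep)))
  for (i in seq_len(nrow(keep))) {
    x[, , i] <- assemble_channels(keep[i, ], tracks, datasets, l_max,
      rbp_panel, postar3_sum)
  }
  structure(
    list(
      x = x,
      label = factor(ifelse(keep$gene_id %in% positive, "positive", "negative"),
        levels = c("negative", "positive")),
      gene_id = keep$gene_id,
      true_length = keep$length,
      manifest = manifest,
      datasets = datasets
    ),
    class = "smoops_encoded"
  )
}

#' @export
print.smoops_encoded <- function(x, ...) {
  cat(sprintf("Encoded cohort: %d examples, %d channels x %d positions (%s)\n",
    dim(x$x)[3], dim(x$x)[1], dim(x$x)[2], paste(x$datasets, collapse = "+")))
  print(table(x$label))
  invisible(x)
}

#' Restrict an encoded cohort to a dataset subset
#'
#' Selects the canonical channels of `datasets` from a larger encoded
#' tensor, so one encoding pass serves every powerset subset.
#'
#' @param encoded A `smoops_encoded` object.
#' @param datasets Dataset subset to keep.
#' @param rbp_panel Panel RBP names (for `postar3`).
#' @param postar3_sum Keep the summed panel channel.
#' @return A `smoops_encoded` object with the reduced channel set.
#' @export
subset_channels <- function(encoded, datasets, rbp_panel = character(),
                            postar3_sum = TRUE) {
  manifest <- channel_manifest(datasets, rbp_panel, postar3_sum)
  missing <- setdiff(manifest, encoded$manifest)
  if (length(missing)) {
    abort(sprintf("channel(s) not in encoded data: %s", paste(missing, collapse = ", ")))
  }
  out <- encoded
  out$x <- encoded$x[match(manifest, encoded$manifest), , , drop = FALSE]
  out$manifest <- manifest
  out$datasets <- datasets
  out
}

#' Length-only baseline encoding
#'
#' A single channel holding 1 for real positions and the -1 pad after, so
#' transcript length is the only information available to the model.
#'
#' @param transcripts Transcript tibble.
#' @param positive,negative Gene id sets.
#' @param max_len,l_max See [encode_dataset()].
#' @return A `smoops_encoded` object with one channel `length_mask`.
#' @export
encode_length_baseline <- function(transcripts, positive, negative,
                                   max_len = 20000, l_max = NULL) {
  keep <- transcripts |>
    dplyr::filter(.data$gene_id %in% c(positive, negative), .data$length <= max_len)
  if (nrow(keep) == 0) abort("no transcripts to encode")
  if (is.null(l_max)) l_max <- max(keep$length)
  x <- array(-1, dim = c(1, l_max, nrow(keep)))
  for (i in seq_len(nrow(keep))) x[1, seq_len(keep$length[i]), i] <- 1
  structure(
    list(
      x = x,
      label = factor(ifelse(keep$gene_id %in% positive, "positive", "negative"),
        levels = c("negative", "positive")),
      gene_id = keep$gene_id,
      true_length = keep$length,
      manifest = "length_mask",
      datasets = "length"
    ),
    class = "smoops_encoded"
  )
}

#' Stratified split with minority oversampling
#'
#' Splits examples into train/validation/test at the given ratios with
#' stratified class proportions (within one example), then oversamples the
#' minority class with replacement within each subset until classes balance.
#'
#' @param labels Factor/character vector of class labels (2 classes, >= 2
#'   examples each), or a `smoops_encoded` object.
#' @param ratios Train/validation/test fractions (sum to 1).
#' @param seed Integer seed.
#' @return An object of class `smoops_split`: list with `train`,
#'   `validation`, `test` (index vectors) and `train_bal`, `validation_bal`,
#'   `test_bal` (balanced index vectors with oversampling).
#' @export
split_and_balance <- function(labels, ratios = c(0.70, 0.15, 0.15), seed = 1L) {
  if (inherits(labels, "smoops_encoded")) labels <- labels$label
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) < 2 || any(table(labels) < 2)) {
    abort("need at least 2 examples in each of 2 classes")
  }
  if (abs(sum(ratios) - 1) > 1e-8) abort("`ratios` must sum to 1")
  with_seed(seed, {
    sets <- list(train = integer(), validation = integer(), test = integer())
    for (cl in levels(labels)) {
      idx <- sample(which(labels == cl))
      n <- length(idx)
      # largest-remainder apportionment keeps strata within one example
      raw <- ratios * n
      base <- floor(raw)
      rem <- n - sum(base)
      if (rem > 0) {
        extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      cuts <- cumsum(c(0, base))
      take <- function(k) if (base[k] == 0) integer() else idx[(cuts[k] + 1):cuts[k + 1]]
      sets$train <- c(sets$train, take(1))
      sets$validation <- c(sets$validation, take(2))
      sets$test <- c(sets$test, take(3))
    }
    balance <- function(idx) {
      tab <- table(labels[idx])
      if (any(tab == 0)) return(idx)
      minority <- names(tab)[which.min(tab)]
      need <- max(tab) - min(tab)
      if (need == 0) return(idx)
      pool <- idx[labels[idx] == minority]
      c(idx, sample(pool, need, replace = TRUE))
    }
    structure(
      list(
        train = sets$train, validation = sets$validation, test = sets$test,
        train_bal = balance(sets$train),
        validation_bal = balance(sets$validation),
        test_bal = balance(sets$test),
        ratios = ratios
      ),
      class = "smoops_split"
    )
  })
}

#' Pick one representative transcript per gene from an expression table
#'
#' Keeps, per gene, the most highly expressed transcript (by the supplied
#' per-stage TPM columns, summed); among transcripts tied for the highest
#' expression at any stage the longest isoform wins.
#'
#' @param tx_table Tibble `gene_id`, `transcript_id`, `length`, plus one TPM
#'   column per stage.
#' @param tpm_cols Names of the TPM columns.
#' @return The filtered tibble, one row per gene.
#' @export
select_representative_transcripts <- function(tx_table, tpm_cols) {
  tx_table |>
    dplyr::mutate(.max_tpm = purrr::reduce(
      purrr::map(tpm_cols, ~ tx_table[[.x]]), pmax)) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(.data$.max_tpm == max(.data$.max_tpm)) |>
    dplyr::filter(.data$length == max(.data$length)) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".max_tpm")
}
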