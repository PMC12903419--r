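# Plain-text interchange: FASTA + BED12 transcript models, TSV enrichment /
# hybrid / protein tables, bedGraph-like track files, one-gene-per-line sets.

#' Write transcript sequences as FASTA
#'
#' @param transcripts Transcript tibble.
#' @param path Output path.
#' @param rna Write U instead of T.
#' @return `path`, invisibly.
#' @export
write_transcripts_fasta <- function(transcripts, path, rna = FALSE) {
  seqs <- if (rna) rna_sequence(transcripts$sequence) else transcripts$sequence
  lines <- as.vector(rbind(paste0(">", transcripts$gene_id), seqs))
  writeLines(lines, path)
  invisible(path)
}

#' Write transcript models as BED12
#'
#' 0-based half-open genomic coordinates; one line per transcript with exon
#' block sizes and starts.
#'
#' @param transcripts Transcript tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transcripts_bed12 <- function(transcripts, path) {
  lines <- purrr::map_chr(seq_len(nrow(transcripts)), function(i) {
    tx <- transcripts[i, ]
    starts <- tx$exon_starts[[1]]
    ends <- tx$exon_ends[[1]]
    chrom_start <- min(starts)
    chrom_end <- max(ends)
    # thickStart/thickEnd mark the CDS in genomic coordinates (+ strand)
    if (!is.na(tx$utr5_len)) {
      cds_tx <- c(tx$utr5_len, tx$utr5_len + tx$cds_len)
      offsets <- cumsum(c(0L, ends - starts))
      tx2gen <- function(p) {
        e <- findInterval(p, offsets, rightmost.closed = FALSE)
        starts[e] + (p - offsets[e])
      }
      thick <- c(tx2gen(cds_tx[1]), tx2gen(cds_tx[2] - 1L) + 1L)
    } else {
      thick <- c(chrom_start, chrom_start)
    }
    paste(
      tx$chrom, chrom_start, chrom_end, tx$gene_id, 0, tx$strand,
      thick[1], thick[2], "0,0,0", length(starts),
      paste0(paste(ends - starts, collapse = ","), ","),
      paste0(paste(starts - chrom_start, collapse = ","), ","),
      sep = "\t"
    )
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED12 file into a transcript-model tibble
#'
#' @param path BED12 path.
#' @return A tibble `gene_id`, `chrom`, `strand`, `exon_starts`, `exon_ends`,
#'   `length`.
#' @export
read_transcripts_bed12 <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  purrr::map_dfr(lines, function(f) {
    chrom_start <- as.integer(f[2])
    sizes <- as.integer(strsplit(f[11], ",")[[1]])
    offs <- as.integer(strsplit(f[12], ",")[[1]])
    starts <- chrom_start + offs
    tibble(
      gene_id = f[4], chrom = f[1], strand = f[6],
      exon_starts = list(starts), exon_ends = list(starts + sizes),
      length = sum(sizes)
    )
  })
}

#' Write/read the enrichment table as TSV
#'
#' Columns `gene_id`, `stage`, `assay`, `lfc`, `padj`.
#'
#' @param table Enrichment tibble.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_enrichment_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment_tsv
#' @export
read_enrichment_tsv <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE))
}

#' Write/read hybrid records as TSV
#'
#' Columns `gene_a`, `gene_b`, `count`, `kind`.
#'
#' @param records Hybrid tibble.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_hybrids_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hybrids_tsv
#' @export
read_hybrids_tsv <- function(path) {
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
    stringsAsFactors = FALSE))
}

#' Write per-transcript tracks as bedGraph-like TSV
#'
#' One row per maximal run of equal signal: `chrom`, `start`, `end`, `score`
#' (0-based half-open, transcript coordinates on the gene's contig mapped
#' through its exons).
#'
#' @param tracks Track tibble.
#' @param transcripts Transcript tibble (for exon coordinates).
#' @param track Track name to export.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(tracks, transcripts, track, path) {
  rows <- tracks[tracks$track == track, ]
  lines <- unlist(purrr::map(seq_len(nrow(rows)), function(i) {
    g <- rows$gene_id[i]
    tx <- transcripts[transcripts$gene_id == g, ]
    v <- rows$values[[i]]
    starts <- tx$exon_starts[[1]]
    ends <- tx$exon_ends[[1]]
    offsets <- cumsum(c(0L, ends - starts))
    out <- character()
    for (e in seq_along(starts)) {
      seg <- v[(offsets[e] + 1):offsets[e + 1]]
      r <- rle(seg)
      stop_at <- cumsum(r$lengths)
      start_at <- c(0L, head(stop_at, -1L))
      keep <- r$values != 0
      if (any(keep)) {
        out <- c(out, paste(tx$chrom, starts[e] + start_at[keep],
          starts[e] + stop_at[keep], r$values[keep], sep = "\t"))
      }
    }
    out
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph-like TSV into an interval tibble
#'
#' @param path File path (columns chrom, start, end, score; no header).
#' @return A tibble `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
    col.names = c("chrom", "start", "end", "score"),
    stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Read gene sets from one-gene-per-line text files
#'
#' @param paths Named character vector of file paths; names become set names.
#' @return A named list of character vectors.
#' @export
read_gene_sets <- function(paths) {
  purrr::map(as.list(paths), function(p) {
    x <- trimws(readLines(p))
    x[nzchar(x)]
  })
}

#' Write a gene set as a one-gene-per-line text file
#'
#' @param genes Character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}
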