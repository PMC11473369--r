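#' Read a count matrix from TSV
#'
#' Expects a header row; the first column is `feature_id`, an optional
#' `feature_length` column carries lengths in nt, and all remaining
#' columns are per-sample counts. Malformed rows are reported with their
#' line numbers.
#'
#' @param path TSV file.
#' @return A [CountMatrix()].
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count table needs feature_id plus >= 1 sample")
  ids <- as.character(df[[1]])
  dup <- which(duplicated(ids))
  if (length(dup)) {
    stop("duplicated feature_id at line(s): ",
         paste(dup + 1L, collapse = ", "))  # +1 for the header line
  }
  lengths <- NULL
  if ("feature_length" %in% names(df)) {
    lengths <- setNames(as.numeric(df$feature_length), ids)
    df$feature_length <- NULL
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric count column in ", path)
  neg <- which(apply(m < 0, 1, any))
  if (length(neg)) {
    stop("negative count at line(s): ", paste(neg + 1L, collapse = ", "))
  }
  rownames(m) <- ids
  CountMatrix(m, lengths)
}

#' Write a count matrix to TSV
#'
#' @param cm a [CountMatrix()].
#' @param path output TSV.
#' @export
write_counts <- function(cm, path) {
  stopifnot(is(cm, "CountMatrix"))
  df <- data.frame(feature_id = rownames(cm$counts),
                   cm$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(cm$feature_lengths)) {
    df <- cbind(df[1], feature_length = cm$feature_lengths[df$feature_id],
                df[-1])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and validate a sample sheet
#'
#' @param path TSV with columns `sample_id`, `species`, `tissue`, `assay`,
#'   `replicate`, `pairing_key`.
#' @return A [SampleTable()].
#' @export
read_sample_sheet <- function(path) {
  SampleTable(read.delim(path, stringsAsFactors = FALSE))
}

#' Write a sample sheet
#' @param samples a [SampleTable()].
#' @param path output TSV.
#' @export
write_sample_sheet <- function(samples, path) {
  write.table(as.data.frame(samples), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read gene/ORF models from GTF or BED12
#'
#' Coordinates are converted to the package-internal 0-based half-open
#' convention at this boundary (GTF is 1-based closed on disk); writing
#' with [write_features()] converts back, so a round trip is lossless.
#' BED12 blocks are validated against the feature span and returned as
#' 0-based half-open genomic intervals in a `blocks` list-column.
#'
#' @param path GTF (`.gtf`) or BED (`.bed`) file.
#' @return `FeatureTable` data.frame: `feature_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, plus `blocks` for BED12 input.
#' @export
read_features <- function(path) {
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "bed"
  gr <- rtracklayer::import(path, format = fmt)
  df <- data.frame(
    feature_id = if (fmt == "gtf") {
      as.character(S4Vectors::mcols(gr)$gene_id)
    } else {
      as.character(S4Vectors::mcols(gr)$name)
    },
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  if (fmt == "bed" && !is.null(S4Vectors::mcols(gr)$blocks)) {
    rel <- S4Vectors::mcols(gr)$blocks
    blocks <- vector("list", length(gr))
    for (i in seq_along(gr)) {
      b <- rel[[i]]
      abs_start <- df$start[i] + IRanges::start(b) - 1L
      abs_end <- df$start[i] + IRanges::end(b)
      if (any(abs_start < df$start[i]) || any(abs_end > df$end[i])) {
        stop("BED12 block outside feature span at line ", i)
      }
      blocks[[i]] <- cbind(start = abs_start, end = abs_end)
    }
    df$blocks <- I(blocks)
  }
  message("read ", nrow(df), " features from ", basename(path))
  df
}

#' Write gene/ORF models to GTF or BED12
#'
#' @param features a `FeatureTable` data.frame (0-based half-open
#'   coordinates, optional `blocks` list-column).
#' @param path output file; extension selects the format.
#' @export
write_features <- function(features, path) {
  fmt <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "bed"
  gr <- GenomicRanges::GRanges(
    seqnames = features$chrom,
    ranges = IRanges::IRanges(start = features$start + 1L,  # to 1-based
                              end = features$end),
    strand = features$strand)
  if (fmt == "gtf") {
    S4Vectors::mcols(gr)$source <- "ribevol"
    S4Vectors::mcols(gr)$type <- "exon"
    S4Vectors::mcols(gr)$gene_id <- features$feature_id
  } else {
    S4Vectors::mcols(gr)$name <- features$feature_id
    if (!is.null(features$blocks)) {
      S4Vectors::mcols(gr)$blocks <- IRanges::IRangesList(
        lapply(seq_len(nrow(features)), function(i) {
          b <- features$blocks[[i]]
          IRanges::IRanges(start = b[, "start"] - features$start[i] + 1L,
                           end = b[, "end"] - features$start[i])
        }))
    }
  }
  rtracklayer::export(gr, path, format = fmt)
  invisible(path)
}

#' Read sequences from FASTA
#' @param path FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by sequence name.
#' @export
read_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Write sequences to FASTA
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(unlist(seqs))
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Strand-aware sequence extraction
#'
#' Extracts `[start, end)` (0-based half-open) from a chromosome and
#' reverse-complements it for minus-strand features.
#'
#' @param seqs a `DNAStringSet` (e.g. from [read_fasta()]).
#' @param chrom sequence name.
#' @param start,end 0-based half-open coordinates.
#' @param strand `"+"` or `"-"`.
#' @return Character sequence in transcription orientation.
#' @export
extract_feature_seq <- function(seqs, chrom, start, end, strand = "+") {
  s <- Biostrings::subseq(seqs[[chrom]], start + 1L, end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}

.outfmt6_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read BLAST tabular hits (outfmt 6)
#'
#' @param path headerless 12-column BLAST tabular file.
#' @return data.frame with standard outfmt-6 column names; `evalue` and
#'   `bitscore` numeric.
#' @export
read_hits <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) != 12) {
    stop("expected 12 BLAST outfmt-6 columns, found ", ncol(df))
  }
  names(df) <- .outfmt6_cols
  for (col in c("pident", "evalue", "bitscore")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  bad <- which(!is.finite(df$evalue))
  if (length(bad)) {
    stop("unparseable E-value at line(s): ", paste(bad, collapse = ", "))
  }
  df
}

#' Write BLAST tabular hits (outfmt 6)
#' @param hits data.frame with outfmt-6 columns.
#' @param path output file (headerless, tab separated).
#' @export
write_hits <- function(hits, path) {
  write.table(hits[, .outfmt6_cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a coordinate-mapping (liftover summary) table
#'
#' @param path TSV with columns `feature_id`, `source_species`,
#'   `target_species`, `target_chrom`, `target_start`, `target_end`,
#'   `target_strand`, `colinear_flag`.
#' @return Validated data.frame.
#' @export
read_mapping <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  req <- c("feature_id", "source_species", "target_species", "target_chrom",
           "target_start", "target_end", "target_strand", "colinear_flag")
  missing_col <- setdiff(req, names(df))
  if (length(missing_col)) {
    stop("mapping table missing column(s): ",
         paste(missing_col, collapse = ", "))
  }
  df$colinear_flag <- as.logical(df$colinear_flag)
  df
}

#' Write a set of result tables to a directory
#'
#' Each element of `tables` is written as `<name>.tsv` under `outdir`.
#'
#' @param tables named list of data.frames.
#' @param outdir output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_results <- function(tables, outdir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    stop("tables must be a named list")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(tables), function(nm) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(as.data.frame(tables[[nm]]), p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
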