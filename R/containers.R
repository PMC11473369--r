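#' Count matrix container
#'
#' A matrix of non-negative integer counts (features x samples) with
#' optional feature lengths in nucleotides. All pipeline readers and the
#' simulator produce this container.
#'
#' @param counts numeric matrix of non-negative, finite counts with
#'   feature row names and sample column names.
#' @param feature_lengths optional named vector of positive feature
#'   lengths (nt); names must cover all rows of `counts`.
#'
#' @return An object of class `CountMatrix`: a list with elements
#'   `counts` and `feature_lengths`.
#' @examples
#' cm <- CountMatrix(matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2"))))
#' dim(cm$counts)
#' @export
CountMatrix <- function(counts, feature_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have feature row names and sample column names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicated feature_id in counts")
  if (anyDuplicated(colnames(counts))) stop("duplicated sample_id in counts")
  if (!is.numeric(counts) || any(!is.finite(counts))) {
    stop("counts must be finite numbers")
  }
  if (any(counts < 0)) stop("negative count encountered")
  if (!is.null(feature_lengths)) {
    if (is.null(names(feature_lengths))) stop("feature_lengths must be named")
    missing_len <- setdiff(rownames(counts), names(feature_lengths))
    if (length(missing_len)) {
      stop("missing length for feature(s): ",
           paste(head(missing_len, 5), collapse = ", "))
    }
    feature_lengths <- feature_lengths[rownames(counts)]
    if (any(!is.finite(feature_lengths)) || any(feature_lengths <= 0)) {
      stop("feature_lengths must be positive and finite")
    }
  }
  structure(list(counts = counts, feature_lengths = feature_lengths),
            class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d features x %d samples%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$feature_lengths)) "" else " (with lengths)"))
  invisible(x)
}

#' Sample sheet container
#'
#' Validates the experiment's sample metadata. Each Ribo-seq sample is
#' linked to its matched RNA-seq sample of the same species and tissue
#' through `pairing_key`; TE is computed per pair.
#'
#' @param df data.frame with columns `sample_id`, `species`, `tissue`,
#'   `assay` (values `"RNA"` or `"RIBO"`), `replicate`, `pairing_key`.
#'
#' @return The validated data.frame with class `SampleTable` prepended.
#' @export
SampleTable <- function(df) {
  req <- c("sample_id", "species", "tissue", "assay", "replicate",
           "pairing_key")
  missing_col <- setdiff(req, names(df))
  if (length(missing_col)) {
    stop("sample sheet missing column(s): ", paste(missing_col, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in sample sheet")
  bad_assay <- setdiff(unique(df$assay), c("RNA", "RIBO"))
  if (length(bad_assay)) {
    stop("unknown assay label(s): ", paste(bad_assay, collapse = ", "))
  }
  ribo <- df[df$assay == "RIBO", , drop = FALSE]
  rna <- df[df$assay == "RNA", , drop = FALSE]
  for (i in seq_len(nrow(ribo))) {
    match_rna <- rna[rna$pairing_key == ribo$pairing_key[i], , drop = FALSE]
    if (nrow(match_rna) != 1L) {
      stop("RIBO sample '", ribo$sample_id[i], "' must pair with exactly ",
           "one RNA sample (found ", nrow(match_rna), ")")
    }
    if (match_rna$species != ribo$species[i] ||
        match_rna$tissue != ribo$tissue[i]) {
      stop("RIBO sample '", ribo$sample_id[i],
           "' pairs with an RNA sample of different species/tissue")
    }
  }
  class(df) <- c("SampleTable", "data.frame")
  df
}

#' @export
print.SampleTable <- function(x, ...) {
  cat(sprintf("SampleTable: %d samples, %d species, assays: %s\n",
              nrow(x), length(unique(x$species)),
              paste(sort(unique(x$assay)), collapse = "/")))
  invisible(x)
}

#' @export
print.NormalizedMatrix <- function(x, ...) {
  cat(sprintf("NormalizedMatrix: %d features x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
print.TEMatrix <- function(x, ...) {
  cat(sprintf("TEMatrix (%s scale): %d genes x %d sample pairs, %d species\n",
              x$scale, nrow(x$te), ncol(x$te), length(unique(x$pairs$species))))
  invisible(x)
}
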