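#' Adjust counts by feature length
#'
#' Divides each feature's counts by its length in kilobases. In the TE
#' workflow this is applied to raw CDS counts *before* cross-sample
#' size-factor normalization, so that species with different CDS lengths
#' are comparable.
#'
#' @param cm a [CountMatrix()] with `feature_lengths` set.
#' @return A `CountMatrix`-shaped object whose `counts` are real-valued
#'   length-adjusted counts (counts per kb of feature).
#' @examples
#' cm <- CountMatrix(matrix(100, 1, 1, dimnames = list("g", "s")),
#'                   feature_lengths = c(g = 500))
#' length_adjust(cm)$counts  # 200
#' @export
length_adjust <- function(cm) {
  stopifnot(is(cm, "CountMatrix"))
  if (is.null(cm$feature_lengths)) {
    stop("length_adjust requires feature_lengths")
  }
  adj <- cm$counts / (cm$feature_lengths[rownames(cm$counts)] / 1000)
  structure(list(counts = adj, feature_lengths = cm$feature_lengths),
            class = "CountMatrix")
}

#' Median-of-ratios size factors
#'
#' Computes one positive size factor per sample using the median-of-ratios
#' method: each sample's counts are divided by the per-gene geometric mean
#' across samples (the pseudo-reference), and the sample's factor is the
#' median of those ratios over reference genes. Reference genes are those
#' with no zero count in any sample. With an even number of reference
#' genes, the median is the mean of the two central ratios.
#'
#' Size factors are computed jointly across all samples (and hence all
#' species) of one assay; RNA and Ribo assays are normalized separately.
#'
#' @param cm a [CountMatrix()] (raw or length-adjusted counts).
#' @return Named numeric vector of size factors, one per sample.
#' @examples
#' m <- matrix(c(1, 2, 4, 2, 4, 8), ncol = 2,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(CountMatrix(m))  # (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(cm) {
  stopifnot(is(cm, "CountMatrix"))
  counts <- cm$counts
  ref <- rowSums(counts == 0) == 0
  if (!any(ref)) {
    stop("no reference gene with all-positive counts; consider a ",
         "pseudo-reference fallback (filter all-zero samples or pool genes)")
  }
  geo <- exp(rowMeans(log(counts[ref, , drop = FALSE])))
  sf <- apply(counts[ref, , drop = FALSE], 2, function(col) {
    median(col / geo)  # even reference count: mean of the two central ratios
  })
  if (any(!is.finite(sf)) || any(sf <= 0)) {
    stop("non-finite or non-positive size factor computed")
  }
  sf
}

#' Normalize a count matrix by size factors
#'
#' @param cm a [CountMatrix()].
#' @param sf optional size factors; computed with [size_factors()] when
#'   missing.
#' @return An object of class `NormalizedMatrix`: list with `values`
#'   (counts divided by size factors), `counts` (the input counts),
#'   `size_factors` and `feature_lengths`.
#' @export
normalize_counts <- function(cm, sf = NULL) {
  stopifnot(is(cm, "CountMatrix"))
  if (is.null(sf)) sf <- size_factors(cm)
  sf <- sf[colnames(cm$counts)]
  if (any(is.na(sf))) stop("size factors missing for some samples")
  values <- sweep(cm$counts, 2, sf, "/")
  structure(list(values = values, counts = cm$counts, size_factors = sf,
                 feature_lengths = cm$feature_lengths),
            class = "NormalizedMatrix")
}

#' Fragments per kilobase per million mapped reads
#'
#' `FPKM[g,s] = count[g,s] / (length_kb_g * libsize_millions_s)`. Library
#' sizes default to the column sums of the count matrix; callers with
#' externally known mapped-read totals can supply them.
#'
#' @param cm a [CountMatrix()] with `feature_lengths`.
#' @param lib_sizes optional named vector of mapped-read totals per
#'   sample; defaults to `colSums(cm$counts)`.
#' @return Numeric matrix of FPKM values, same dimnames as the counts.
#' @examples
#' cm <- CountMatrix(matrix(100, 1, 1, dimnames = list("g", "s")),
#'                   feature_lengths = c(g = 1000))
#' fpkm(cm, lib_sizes = c(s = 1e6))  # 100
#' @export
fpkm <- function(cm, lib_sizes = NULL) {
  stopifnot(is(cm, "CountMatrix"))
  if (is.null(cm$feature_lengths)) stop("fpkm requires feature_lengths")
  if (is.null(lib_sizes)) lib_sizes <- colSums(cm$counts)
  lib_sizes <- lib_sizes[colnames(cm$counts)]
  if (any(is.na(lib_sizes)) || any(lib_sizes <= 0)) {
    stop("library sizes must be positive for every sample")
  }
  len_kb <- cm$feature_lengths[rownames(cm$counts)] / 1000
  sweep(cm$counts / len_kb, 2, lib_sizes / 1e6, "/")
}
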