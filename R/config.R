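#' Pipeline configuration with study-default thresholds
#'
#' All thresholds used by the pipeline are configurable; the defaults are
#' the values used throughout the package documentation and tests.
#'
#' @param ... named overrides of any default listed below.
#'
#' @return A named list of class `ribevol_config` with elements:
#' \describe{
#'   \item{fpkm_min_rep}{per-replicate FPKM floor for the active-gene
#'     filter (default 0.5).}
#'   \item{fpkm_mean_min}{mean-FPKM floor for the active-gene filter
#'     (default 1.0).}
#'   \item{min_reps}{minimum replicates passing `fpkm_min_rep`, and the
#'     minimum samples an ORF must be predicted in (default 3).}
#'   \item{tau_cutoff}{tau above which a gene is tissue enriched
#'     (default 0.75, strict `>`).}
#'   \item{fc_cutoff}{minimum absolute linear fold change for differential
#'     expression (default 1.5).}
#'   \item{alpha}{adjusted-p cutoff for differential expression
#'     (default 0.05).}
#'   \item{overlap_collapse}{fraction of the shorter ORF's in-frame
#'     positions that must be shared for two ORFs to collapse
#'     (default 0.9).}
#'   \item{truncation_cutoff}{minimum truncated fraction of the in-frame
#'     sequence for a de novo structure call (default 0.7).}
#'   \item{evalue_max}{maximum BLAST E-value accepted as a homolog hit
#'     (default 1e-4).}
#'   \item{min_counterpart_reads}{pooled Ribo-seq reads in a counterpart
#'     region at or above which translation is considered present there
#'     (default 10).}
#'   \item{iterations}{default resampling iterations (default 10000).}
#'   \item{rho_cutoff}{minimum absolute Spearman rho for a co-regulation
#'     edge (default 0.5).}
#'   \item{pseudocount}{pseudocount added to normalized counts before
#'     log2 TE ratios (default 1).}
#'   \item{denovo_rule}{"all" (default) or "any": whether the truncation
#'     rule must hold in all aligned species or in at least one.}
#' }
#' @examples
#' cfg <- ribevol_config(tau_cutoff = 0.8)
#' cfg$tau_cutoff
#' @export
ribevol_config <- function(...) {
  cfg <- list(
    fpkm_min_rep = 0.5,
    fpkm_mean_min = 1.0,
    min_reps = 3L,
    tau_cutoff = 0.75,
    fc_cutoff = 1.5,
    alpha = 0.05,
    overlap_collapse = 0.9,
    truncation_cutoff = 0.7,
    evalue_max = 1e-4,
    min_counterpart_reads = 10L,
    iterations = 10000L,
    rho_cutoff = 0.5,
    pseudocount = 1,
    denovo_rule = "all"
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) {
      stop("unknown config option(s): ", paste(bad, collapse = ", "))
    }
    cfg[names(dots)] <- dots
  }
  stopifnot(cfg$denovo_rule %in% c("all", "any"))
  structure(cfg, class = c("ribevol_config", "list"))
}

# shared helper: stop unless x is a single finite number
assert_scalar_number <- function(x, field, min = -Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("field '", field, "' must be a single finite number")
  }
  if (strict_min && x <= min) stop("field '", field, "' must be > ", min)
  if (!strict_min && x < min) stop("field '", field, "' must be >= ", min)
  invisible(x)
}
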