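#' Tau tissue-specificity index
#'
#' For a gene with mean expression `x_i` over `n` tissues,
#' `xhat_i = x_i / max_i(x_i)` and `tau = sum(1 - xhat_i) / (n - 1)`.
#' Tau is 0 for perfectly uniform expression and 1 for single-tissue
#' expression, and is invariant to positive rescaling of a gene's vector.
#' Tissues named in `excluded_tissues` (testis by default, whose pervasive
#' transcription inflates apparent specificity of young genes) are removed
#' before the computation. All-zero genes are skipped with a warning.
#'
#' @param atlas numeric matrix of non-negative mean expression values,
#'   genes x tissues (column names are tissue labels).
#' @param excluded_tissues tissues dropped before computing tau
#'   (default `"testis"`).
#' @param tau_cutoff enrichment cutoff, strict `>` (default 0.75).
#' @return `TauResult` data.frame: `gene_id`, `tau`, `argmax_tissue`
#'   (NA on ties), `enriched`, `cutoff`.
#' @examples
#' m <- rbind(g1 = c(5, 5, 5, 5), g2 = c(0, 0, 7, 0), g3 = c(8, 4, 2, 2))
#' colnames(m) <- paste0("t", 1:4)
#' tau(m, excluded_tissues = character())$tau  # 0, 1, 2/3
#' @export
tau <- function(atlas, excluded_tissues = "testis", tau_cutoff = 0.75) {
  atlas <- as.matrix(atlas)
  keep_tissues <- setdiff(colnames(atlas), excluded_tissues)
  if (length(keep_tissues) < 2) {
    stop("tau requires >= 2 tissues after exclusion (divisor n - 1)")
  }
  x <- atlas[, keep_tissues, drop = FALSE]
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("expression values must be finite and non-negative")
  }
  mx <- apply(x, 1, max)
  zero <- mx == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero gene(s) skipped (tau undefined)")
  }
  n <- ncol(x)
  tau_v <- rowSums(1 - x / mx) / (n - 1)
  tau_v[zero] <- NA_real_
  argmax <- apply(x, 1, function(v) {
    w <- which(v == max(v))
    if (length(w) == 1) keep_tissues[w] else NA_character_
  })
  argmax[zero] <- NA_character_
  data.frame(gene_id = rownames(x),
             tau = tau_v,
             argmax_tissue = argmax,
             enriched = !is.na(tau_v) & tau_v > tau_cutoff & !is.na(argmax),
             cutoff = tau_cutoff,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Genes with recently acquired tissue enrichment
#'
#' Selects orthologous genes that are enriched (`tau > cutoff`) with the
#' focal tissue as their expression maximum in the focal species, and are
#' *not* enriched in that same tissue in any other species. Genes missing
#' a tau result in any comparison species are excluded.
#'
#' @param tau_by_species named list of `TauResult` data.frames (one per
#'   species, gene ids shared across species for orthologs).
#' @param focal_tissue tissue whose enrichment must be recent.
#' @param focal_species species in which the enrichment must hold.
#' @return Character vector of gene ids.
#' @export
recent_tissue_enriched <- function(tau_by_species, focal_tissue,
                                   focal_species) {
  if (!focal_species %in% names(tau_by_species)) {
    stop("focal species absent from tau results")
  }
  focal <- tau_by_species[[focal_species]]
  others <- tau_by_species[setdiff(names(tau_by_species), focal_species)]
  cand <- focal$gene_id[focal$enriched &
                          !is.na(focal$argmax_tissue) &
                          focal$argmax_tissue == focal_tissue]
  covered <- Reduce(intersect, c(list(cand),
                                 lapply(others, `[[`, "gene_id")))
  dropped <- setdiff(cand, covered)
  if (length(dropped)) {
    message(length(dropped), " candidate(s) lacking orthologous tau in a ",
            "comparison species were excluded")
  }
  keep <- vapply(covered, function(g) {
    !any(vapply(others, function(tb) {
      row <- tb[tb$gene_id == g, , drop = FALSE]
      isTRUE(row$enriched && !is.na(row$argmax_tissue) &&
               row$argmax_tissue == focal_tissue)
    }, logical(1)))
  }, logical(1))
  covered[keep]
}

#' Spearman co-regulation network around focus genes
#'
#' Computes Spearman correlations between each focus gene and all other
#' genes over pairwise-complete observations of normalized expression.
#' Genes detected (at least one raw count) in fewer than `min_samples`
#' samples are excluded, as are self-edges and pairs where either vector
#' is constant (rho undefined). Edges are retained when
#' `|rho| > rho_cutoff`.
#'
#' @param norm a `NormalizedMatrix` (values used for ranks, raw counts for
#'   the detection filter).
#' @param focus gene ids whose partner sets are wanted.
#' @param min_samples minimum samples with a raw count for a gene to enter
#'   the network (e.g. 20 for a human-sized atlas, 10 for a smaller one).
#' @param rho_cutoff minimum absolute Spearman rho (default 0.5, strict).
#' @return `CoexpressionEdge` data.frame: `gene_a` (focus), `gene_b`,
#'   `spearman_rho`, `n_pairs_used`.
#' @export
coexpression_network <- function(norm, focus, min_samples = 10L,
                                 rho_cutoff = 0.5) {
  stopifnot(is(norm, "NormalizedMatrix"))
  detected <- rowSums(norm$counts >= 1) >= min_samples
  m <- norm$values[detected, , drop = FALSE]
  focus <- intersect(focus, rownames(m))
  if (!length(focus)) stop("no focus gene passes the detection filter")
  tm <- t(m)
  edges <- list()
  for (g in focus) {
    x <- m[g, ]
    rho <- suppressWarnings(
      cor(x, tm, method = "spearman", use = "pairwise.complete.obs"))[1, ]
    n_used <- colSums(is.finite(tm) & is.finite(x))
    const <- apply(tm, 2, function(v) {
      ok <- is.finite(v) & is.finite(x)
      sum(ok) < 3 || sd(v[ok]) == 0
    })
    keep <- !is.na(rho) & abs(rho) > rho_cutoff & names(rho) != g & !const
    if (!any(keep)) next
    edges[[length(edges) + 1L]] <- data.frame(
      gene_a = g, gene_b = names(rho)[keep], spearman_rho = rho[keep],
      n_pairs_used = n_used[keep], stringsAsFactors = FALSE)
  }
  if (!length(edges)) {
    return(data.frame(gene_a = character(), gene_b = character(),
                      spearman_rho = numeric(), n_pairs_used = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
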