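#' Construct a TE matrix from precomputed values
#'
#' Wraps an externally computed TE table (e.g. imported from another
#' pipeline) in the container [compute_te()] produces, so all downstream
#' inference functions accept it.
#'
#' @param te numeric matrix, genes x sample pairs (row and column names
#'   required).
#' @param species species label per column (recycled names are not
#'   allowed; length must equal `ncol(te)`).
#' @param scale `"log2"` or `"linear"`.
#' @param pseudocount pseudocount used when the values were computed.
#' @return A `TEMatrix`.
#' @export
te_matrix <- function(te, species, scale = c("log2", "linear"),
                      pseudocount = 0) {
  scale <- match.arg(scale)
  te <- as.matrix(te)
  if (length(species) != ncol(te)) {
    stop("species must have one label per TE column")
  }
  if (is.null(rownames(te)) || is.null(colnames(te))) {
    stop("te must have gene row names and pair column names")
  }
  pairs <- data.frame(pair_id = colnames(te), species = species,
                      tissue = NA_character_, rna_sample = NA_character_,
                      ribo_sample = NA_character_, stringsAsFactors = FALSE)
  structure(list(te = te, scale = scale, pseudocount = pseudocount,
                 pairs = pairs, filtered = character()),
            class = "TEMatrix")
}

#' Per-sample translational efficiency
#'
#' TE is the ratio of normalized in-frame Ribo-seq P-site counts to
#' normalized RNA-seq counts, computed per matched RNA/Ribo sample pair.
#' Both matrices are expected to be length-adjusted and size-factor
#' normalized ([length_adjust()], [normalize_counts()]).
#'
#' Genes failing the per-species zero filter are dropped from the matrix
#' before any TE value is emitted: a gene is excluded when, within any
#' species and either assay, its raw replicate counts have a median of 0
#' or contain 3 or more zeros.
#'
#' @param rna,ribo `NormalizedMatrix` objects for the RNA and Ribo assays
#'   (from [normalize_counts()]); both retain the raw counts used by the
#'   zero filter.
#' @param samples a [SampleTable()] describing both assays; every RIBO
#'   sample must pair to an RNA sample through `pairing_key`.
#' @param scale `"log2"` (default) or `"linear"`.
#' @param pseudocount added to both normalized counts before the ratio
#'   (default 1); set to 0 to take the plain ratio.
#' @param max_zero_reps zeros within a species' replicates at or above
#'   which the gene is excluded (default 3).
#'
#' @return An object of class `TEMatrix`: list with `te` (genes x sample
#'   pairs), `scale`, `pseudocount`, `pairs` (data.frame with `pair_id`,
#'   `species`, `tissue`, `rna_sample`, `ribo_sample`) and `filtered`
#'   (ids of genes removed by the zero rule).
#' @export
compute_te <- function(rna, ribo, samples, scale = c("log2", "linear"),
                       pseudocount = 1, max_zero_reps = 3L) {
  scale <- match.arg(scale)
  stopifnot(is(rna, "NormalizedMatrix"), is(ribo, "NormalizedMatrix"))
  samples <- SampleTable(samples)

  ribo_meta <- samples[samples$assay == "RIBO", , drop = FALSE]
  rna_meta <- samples[samples$assay == "RNA", , drop = FALSE]
  missing_ribo <- setdiff(ribo_meta$sample_id, colnames(ribo$values))
  if (length(missing_ribo)) {
    stop("RIBO sample(s) absent from ribo matrix: ",
         paste(missing_ribo, collapse = ", "))
  }
  rna_of <- rna_meta$sample_id[match(ribo_meta$pairing_key,
                                     rna_meta$pairing_key)]
  if (any(is.na(rna_of)) || length(setdiff(rna_of, colnames(rna$values)))) {
    stop("unpaired RIBO sample: pairing_key does not resolve to an RNA ",
         "sample present in the rna matrix")
  }

  genes <- intersect(rownames(rna$values), rownames(ribo$values))
  if (!length(genes)) stop("no shared genes between rna and ribo matrices")

  # per-species zero rule on raw counts, each assay checked separately
  drop <- rep(FALSE, length(genes))
  names(drop) <- genes
  for (sp in unique(ribo_meta$species)) {
    rna_cols <- rna_of[ribo_meta$species == sp]
    ribo_cols <- ribo_meta$sample_id[ribo_meta$species == sp]
    for (raw in list(rna$counts[genes, rna_cols, drop = FALSE],
                     ribo$counts[genes, ribo_cols, drop = FALSE])) {
      med0 <- apply(raw, 1, median) == 0
      nzero <- rowSums(raw == 0)
      drop <- drop | med0 | (nzero >= max_zero_reps)
    }
  }
  keep <- genes[!drop]
  if (!length(keep)) stop("all genes removed by the zero-count filter")

  num <- ribo$values[keep, ribo_meta$sample_id, drop = FALSE] + pseudocount
  den <- rna$values[keep, rna_of, drop = FALSE] + pseudocount
  te <- num / den
  if (scale == "log2") te <- log2(te)
  colnames(te) <- ribo_meta$pairing_key

  pairs <- data.frame(pair_id = ribo_meta$pairing_key,
                      species = ribo_meta$species,
                      tissue = ribo_meta$tissue,
                      rna_sample = rna_of,
                      ribo_sample = ribo_meta$sample_id,
                      stringsAsFactors = FALSE)
  structure(list(te = te, scale = scale, pseudocount = pseudocount,
                 pairs = pairs, filtered = genes[drop]),
            class = "TEMatrix")
}

# core TE_var engine on a TE matrix given a species assignment per column.
# Returns list(te_var, across, avg_sampling, means, n_species) computed for
# every row at once; species with fewer than 2 columns are excluded.
.te_var_engine <- function(te, species) {
  species <- as.character(species)
  n_by_sp <- table(species)
  use_sp <- names(n_by_sp)[n_by_sp >= 2L]
  if (length(use_sp) < 2L) {
    stop("need >= 2 species with >= 2 samples each")
  }
  cols <- species %in% use_sp
  te <- te[, cols, drop = FALSE]
  species <- species[cols]
  fac <- factor(species, levels = use_sp)
  k <- length(use_sp)
  n_s <- as.numeric(table(fac))

  ind <- matrix(0, length(species), k)          # n_samples x k membership
  ind[cbind(seq_along(species), as.integer(fac))] <- 1
  sums <- te %*% ind                            # per-species sums
  means <- sweep(sums, 2, n_s, "/")
  sq <- (te * te) %*% ind
  vars <- sweep(sq - sweep(means * means, 2, n_s, "*"), 2, n_s - 1, "/")
  sampling <- sweep(vars, 2, n_s, "/")          # Var/n per species
  avg_sampling <- rowMeans(sampling)
  grand <- rowMeans(means)
  across <- (rowSums(means * means) - k * grand * grand) / (k - 1)
  colnames(means) <- colnames(vars) <- use_sp
  list(te_var = across - avg_sampling, across = across,
       avg_sampling = avg_sampling, means = means, vars = vars,
       species = use_sp, n_s = n_s)
}

#' Between-species TE variance corrected for sampling noise
#'
#' For each gene, computes (1) the per-species sampling variance of TE —
#' the variance across that species' individuals divided by the number of
#' samples — averaged over species, and (2) the variance of per-species
#' mean TE across species. The reported score is
#' `te_var = across_species_variance - avg_sampling_variance`, so genes
#' whose between-species spread exceeds what within-species noise predicts
#' score high. Sample variances use the n-1 denominator at both levels;
#' negative scores are reported, never clamped.
#'
#' Species contributing a single retained sample are excluded from both
#' terms (with a message); genes need at least two remaining species.
#'
#' @param te a `TEMatrix` from [compute_te()].
#' @return A data.frame of class `TEVarResult` with columns `gene_id`,
#'   `across_species_variance`, `avg_sampling_variance`, `te_var`,
#'   `n_species_used`; per-species mean and within-variance matrices are
#'   attached as attributes `species_means` and `species_vars`.
#' @export
te_var <- function(te) {
  stopifnot(is(te, "TEMatrix"))
  sp <- te$pairs$species
  n_by_sp <- table(sp)
  dropped <- names(n_by_sp)[n_by_sp < 2L]
  if (length(dropped)) {
    message("excluding species with a single sample: ",
            paste(dropped, collapse = ", "))
  }
  eng <- .te_var_engine(te$te, sp)
  out <- data.frame(gene_id = rownames(te$te),
                    across_species_variance = eng$across,
                    avg_sampling_variance = eng$avg_sampling,
                    te_var = eng$te_var,
                    n_species_used = length(eng$species),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "species_means") <- eng$means
  attr(out, "species_vars") <- eng$vars
  class(out) <- c("TEVarResult", "data.frame")
  out
}

#' Median TE_var of a gene group
#'
#' @param results a `TEVarResult` data.frame from [te_var()].
#' @param group character vector of gene ids.
#' @return The median `te_var` over group members present in `results`.
#' @export
group_median <- function(results, group) {
  hit <- results$gene_id %in% group
  if (!any(hit)) stop("group has no genes in the TE_var results")
  median(results$te_var[hit])
}

#' Resampling p-values for gene-group TE_var medians
#'
#' Each iteration permutes the sample-to-species assignment globally
#' (whole TE columns are relabeled without replacement, preserving each
#' species' sample count and all gene-gene correlation), recomputes
#' `te_var` for every gene and takes each group's median. The one-sided
#' p-value is the fraction of permuted medians strictly greater than the
#' observed median (ties count as non-exceeding), so its resolution floor
#' is `1/iterations`. P-values are Benjamini-Hochberg adjusted across the
#' tested groups.
#'
#' @param te a `TEMatrix`.
#' @param groups named list of gene-id vectors.
#' @param iterations permutation count (default 10000).
#' @param seed integer seed.
#' @return data.frame with `group`, `n_genes`, `observed_median`,
#'   `p_one_sided`, `fdr_adjusted_p`; the iterations-by-groups matrix of
#'   permuted medians is attached as attribute `resampled_medians`.
#' @export
resample_group_pvalue <- function(te, groups, iterations = 10000L,
                                  seed = 1L) {
  stopifnot(is(te, "TEMatrix"), iterations >= 1L)
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stop("groups must be a named list")
  }
  gene_ids <- rownames(te$te)
  idx <- lapply(groups, function(g) {
    w <- which(gene_ids %in% g)
    if (!length(w)) stop("group absent from TE matrix")
    w
  })
  sp <- te$pairs$species
  obs_tv <- .te_var_engine(te$te, sp)$te_var
  obs_med <- vapply(idx, function(w) median(obs_tv[w]), numeric(1))

  set.seed(seed)
  perm_med <- matrix(NA_real_, iterations, length(groups),
                     dimnames = list(NULL, names(groups)))
  for (i in seq_len(iterations)) {
    tv <- .te_var_engine(te$te, sample(sp))$te_var
    perm_med[i, ] <- vapply(idx, function(w) median(tv[w]), numeric(1))
  }
  p <- colMeans(sweep(perm_med, 2, obs_med, ">"))
  out <- data.frame(group = names(groups),
                    n_genes = lengths(idx),
                    observed_median = obs_med,
                    p_one_sided = p,
                    fdr_adjusted_p = p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "resampled_medians") <- perm_med
  out
}

#' Downsampling confidence interval for a group's TE_var median
#'
#' Each iteration draws `k_samples` sample pairs per species without
#' replacement, recomputes `te_var` and the group median; the 2.5th and
#' 97.5th percentiles of the iteration medians are returned.
#'
#' @param te a `TEMatrix`.
#' @param group character vector of gene ids.
#' @param k_samples samples retained per species each iteration.
#' @param iterations iteration count (default 10000).
#' @param seed integer seed.
#' @return Named numeric vector `c(lower, upper)`; the vector of iteration
#'   medians is attached as attribute `downsampled_medians`.
#' @export
downsample_group_ci <- function(te, group, k_samples, iterations = 10000L,
                                seed = 1L) {
  stopifnot(is(te, "TEMatrix"), k_samples >= 2L)
  gene_idx <- which(rownames(te$te) %in% group)
  if (!length(gene_idx)) stop("group absent from TE matrix")
  sp <- te$pairs$species
  by_sp <- split(seq_along(sp), sp)
  if (k_samples > min(lengths(by_sp))) {
    stop("k_samples exceeds the smallest species' sample count")
  }
  set.seed(seed)
  meds <- vapply(seq_len(iterations), function(i) {
    cols <- unlist(lapply(by_sp, function(w) {
      w[sample.int(length(w), k_samples)]
    }), use.names = FALSE)
    tv <- .te_var_engine(te$te[, cols, drop = FALSE], sp[cols])$te_var
    median(tv[gene_idx])
  }, numeric(1))
  out <- quantile(meds, c(0.025, 0.975), names = FALSE)
  names(out) <- c("lower", "upper")
  attr(out, "downsampled_medians") <- meds
  out
}
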