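#' Simulation configuration for paired RNA/Ribo count tables
#'
#' Describes a multi-species paired Ribo-seq/RNA-seq experiment in which
#' each gene's log2 TE decomposes into a gene-level mean, a species-level
#' shift `B_gs ~ N(0, sigma_between^2)` and a replicate-level shift
#' `W_gsr ~ N(0, sigma_within^2)`. Counts are negative binomial with the
#' mean/dispersion parameterization `Var = mu + mu^2 / dispersion`.
#'
#' Defaults emulate a five-species left-ventricle design (human,
#' chimpanzee, rhesus, mouse, rat with 15/5/4/6/5 biological replicates).
#'
#' @param n_species number of species.
#' @param samples_per_species integer vector of replicate counts, recycled
#'   to `n_species`.
#' @param n_genes number of genes.
#' @param mean_log_expression mean of gene baseline expression (log2
#'   length-normalized counts per unit library).
#' @param dispersion NB shape; larger is closer to Poisson (> 0).
#' @param sigma_between SD of the species-level log2 TE component (>= 0).
#' @param sigma_within SD of the replicate-level log2 TE component (>= 0).
#' @param planted_groups named list; each element
#'   `list(n_genes =, sigma_between =)` plants a gene group with its own
#'   between-species SD.
#' @param planted_regulation named list over modes `buffering`,
#'   `exclusive`, `intensified`; each element
#'   `list(n_genes =, rna_log2fc =, te_log2fc =)` plants genes whose RNA
#'   abundance and TE shift by the given log2 fold changes in the focal
#'   (first) species only.
#' @param libsize_range pair of positive reals; per-sample library scale
#'   factors are drawn log-uniformly from this interval.
#' @param seed integer seed governing all randomness.
#' @return Validated list of class `SimConfig`.
#' @export
sim_config <- function(n_species = 5L,
                       samples_per_species = c(15L, 5L, 4L, 6L, 5L),
                       n_genes = 2000L,
                       mean_log_expression = 7,
                       dispersion = 10,
                       sigma_between = 0.5,
                       sigma_within = 0.5,
                       planted_groups = list(),
                       planted_regulation = list(),
                       libsize_range = c(0.7, 1.4),
                       seed = 1L) {
  assert_scalar_number(n_species, "n_species", min = 2)
  assert_scalar_number(n_genes, "n_genes", min = 1)
  assert_scalar_number(mean_log_expression, "mean_log_expression")
  assert_scalar_number(dispersion, "dispersion", min = 0, strict_min = TRUE)
  assert_scalar_number(sigma_between, "sigma_between", min = 0)
  assert_scalar_number(sigma_within, "sigma_within", min = 0)
  assert_scalar_number(seed, "seed")
  if (length(libsize_range) != 2 || any(!is.finite(libsize_range)) ||
      any(libsize_range <= 0) || libsize_range[1] > libsize_range[2]) {
    stop("field 'libsize_range' must be an ordered pair of positive reals")
  }
  samples_per_species <- rep_len(as.integer(samples_per_species), n_species)
  if (any(!is.finite(samples_per_species)) || any(samples_per_species < 1)) {
    stop("field 'samples_per_species' must be positive counts")
  }
  for (nm in names(planted_groups)) {
    g <- planted_groups[[nm]]
    assert_scalar_number(g$n_genes, paste0("planted_groups$", nm, "$n_genes"),
                         min = 1)
    assert_scalar_number(g$sigma_between,
                         paste0("planted_groups$", nm, "$sigma_between"),
                         min = 0)
  }
  bad_modes <- setdiff(names(planted_regulation),
                       c("buffering", "exclusive", "intensified"))
  if (length(bad_modes)) {
    stop("field 'planted_regulation' has unknown mode(s): ",
         paste(bad_modes, collapse = ", "))
  }
  for (nm in names(planted_regulation)) {
    r <- planted_regulation[[nm]]
    assert_scalar_number(r$n_genes,
                         paste0("planted_regulation$", nm, "$n_genes"), min = 1)
    assert_scalar_number(r$rna_log2fc,
                         paste0("planted_regulation$", nm, "$rna_log2fc"))
    assert_scalar_number(r$te_log2fc,
                         paste0("planted_regulation$", nm, "$te_log2fc"))
  }
  n_planted <- sum(vapply(planted_groups, `[[`, numeric(1), "n_genes")) +
    sum(vapply(planted_regulation, `[[`, numeric(1), "n_genes"))
  if (n_planted > n_genes) {
    stop("planted group/regulation gene counts exceed n_genes")
  }
  structure(list(n_species = as.integer(n_species),
                 samples_per_species = samples_per_species,
                 n_genes = as.integer(n_genes),
                 mean_log_expression = mean_log_expression,
                 dispersion = dispersion,
                 sigma_between = sigma_between,
                 sigma_within = sigma_within,
                 planted_groups = planted_groups,
                 planted_regulation = planted_regulation,
                 libsize_range = libsize_range,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

.default_species <- c("human", "chimp", "rhesus", "mouse", "rat")

#' Simulate paired RNA-seq and Ribo-seq count matrices
#'
#' Draws, for gene g, species s, replicate r:
#' `log2 TE_gsr = mu_g + B_gs + W_gsr`, with
#' `B_gs ~ N(0, sigma_between^2)` and `W_gsr ~ N(0, sigma_within^2)`.
#' RNA counts are `NB(mean = lib_r * len_kb_g * 2^E_gs, dispersion)` and
#' Ribo counts `NB(mean = lib_r * len_kb_g * 2^(E_gs + log2 TE_gsr),
#' dispersion)`, where `E_gs` is the gene's baseline log2 expression
#' (shifted by `rna_log2fc` in the focal species for regulation-mode
#' genes, whose TE is likewise shifted by `te_log2fc`). Library scale
#' factors are drawn log-uniformly per sample and assay and recorded in
#' the truth. The same config and seed always reproduce identical output.
#'
#' @param config a [sim_config()].
#' @return List with elements `rna` and `ribo` ([CountMatrix()] objects
#'   sharing feature lengths), `samples` (a [SampleTable()] covering both
#'   assays) and `truth` (class `SimTruth`): `genes` (per-gene group,
#'   regulation mode, mu, sigma_between, baseline expression),
#'   `species_log2_te` (genes x species matrix of planted
#'   `mu_g + B_gs` plus any focal TE shift), `lib_sizes`, `focal_species`
#'   and the species names.
#' @export
simulate_counts <- function(config) {
  stopifnot(is(config, "SimConfig"))
  set.seed(config$seed)
  n_g <- config$n_genes
  k <- config$n_species
  species <- if (k <= length(.default_species)) {
    .default_species[seq_len(k)]
  } else {
    c(.default_species, paste0("species", seq_len(k - length(.default_species))))
  }
  focal <- species[1]
  genes <- sprintf("gene%05d", seq_len(n_g))

  # gene-level parameters
  lengths_nt <- round(runif(n_g, 300, 3000))
  names(lengths_nt) <- genes
  base_expr <- rnorm(n_g, config$mean_log_expression, 1)
  mu_te <- rnorm(n_g, 0, 0.25)

  group <- rep("background", n_g)
  sigma_b <- rep(config$sigma_between, n_g)
  cursor <- 1L
  for (nm in names(config$planted_groups)) {
    g <- config$planted_groups[[nm]]
    idx <- seq.int(cursor, length.out = g$n_genes)
    group[idx] <- nm
    sigma_b[idx] <- g$sigma_between
    cursor <- cursor + g$n_genes
  }
  reg_mode <- rep("none", n_g)
  rna_fc <- te_fc <- rep(0, n_g)
  for (nm in names(config$planted_regulation)) {
    r <- config$planted_regulation[[nm]]
    idx <- seq.int(cursor, length.out = r$n_genes)
    reg_mode[idx] <- nm
    rna_fc[idx] <- r$rna_log2fc
    te_fc[idx] <- r$te_log2fc
    cursor <- cursor + r$n_genes
  }

  # species-level TE component (genes x species)
  B <- matrix(rnorm(n_g * k, 0, 1), n_g, k) * sigma_b
  species_te <- mu_te + B
  species_te[, 1] <- species_te[, 1] + te_fc
  colnames(species_te) <- species
  rownames(species_te) <- genes

  # samples and library sizes
  sample_meta <- do.call(rbind, lapply(seq_len(k), function(s) {
    data.frame(species = species[s], replicate = seq_len(config$samples_per_species[s]),
               stringsAsFactors = FALSE)
  }))
  n_pairs <- nrow(sample_meta)
  pairing <- sprintf("%s_rep%02d", sample_meta$species, sample_meta$replicate)
  lr <- log(config$libsize_range)
  lib_rna <- exp(runif(n_pairs, lr[1], lr[2]))
  lib_ribo <- exp(runif(n_pairs, lr[1], lr[2]))

  len_kb <- lengths_nt / 1000
  rna_counts <- matrix(0L, n_g, n_pairs)
  ribo_counts <- matrix(0L, n_g, n_pairs)
  for (j in seq_len(n_pairs)) {
    s <- match(sample_meta$species[j], species)
    e_gs <- base_expr + if (s == 1L) rna_fc else 0
    w <- rnorm(n_g, 0, config$sigma_within)
    log2te <- species_te[, s] + w
    mu_rna <- lib_rna[j] * len_kb * 2^e_gs
    mu_ribo <- lib_ribo[j] * len_kb * 2^(e_gs + log2te)
    rna_counts[, j] <- rnbinom(n_g, mu = mu_rna, size = config$dispersion)
    ribo_counts[, j] <- rnbinom(n_g, mu = mu_ribo, size = config$dispersion)
  }
  rna_ids <- paste0(pairing, "_rna")
  ribo_ids <- paste0(pairing, "_ribo")
  dimnames(rna_counts) <- list(genes, rna_ids)
  dimnames(ribo_counts) <- list(genes, ribo_ids)

  samples <- SampleTable(data.frame(
    sample_id = c(rna_ids, ribo_ids),
    species = rep(sample_meta$species, 2),
    tissue = "LV",
    assay = rep(c("RNA", "RIBO"), each = n_pairs),
    replicate = rep(sample_meta$replicate, 2),
    pairing_key = rep(pairing, 2),
    stringsAsFactors = FALSE))

  truth <- structure(list(
    genes = data.frame(gene_id = genes, group = group,
                       regulation_mode = reg_mode,
                       mu_log2_te = mu_te, sigma_between = sigma_b,
                       base_log2_expression = base_expr,
                       rna_log2fc = rna_fc, te_log2fc = te_fc,
                       stringsAsFactors = FALSE),
    species_log2_te = species_te,
    lib_sizes = data.frame(sample_id = c(rna_ids, ribo_ids),
                           assay = rep(c("RNA", "RIBO"), each = n_pairs),
                           lib_size = c(lib_rna, lib_ribo),
                           stringsAsFactors = FALSE),
    focal_species = focal,
    species = species), class = "SimTruth")

  list(rna = CountMatrix(rna_counts, lengths_nt),
       ribo = CountMatrix(ribo_counts, lengths_nt),
       samples = samples,
       truth = truth)
}
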