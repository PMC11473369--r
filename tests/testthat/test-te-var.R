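# minimal paired design builder: counts chosen directly, libsize factors 1
make_paired <- function(rna_counts, ribo_counts, species) {
  n <- ncol(rna_counts)
  pairing <- sprintf("p%02d", seq_len(n))
  colnames(rna_counts) <- paste0(pairing, "_rna")
  colnames(ribo_counts) <- paste0(pairing, "_ribo")
  samples <- SampleTable(data.frame(
    sample_id = c(colnames(rna_counts), colnames(ribo_counts)),
    species = rep(species, 2), tissue = "LV",
    assay = rep(c("RNA", "RIBO"), each = n),
    replicate = rep(seq_len(n), 2), pairing_key = rep(pairing, 2)))
  list(rna = normalize_counts(CountMatrix(rna_counts), sf = setNames(
         rep(1, n), colnames(rna_counts))),
       ribo = normalize_counts(CountMatrix(ribo_counts), sf = setNames(
         rep(1, n), colnames(ribo_counts))),
       samples = samples)
}

test_that("compute_te applies the ratio and the per-species zero rule", {
  rna <- rbind(gA = c(5, 5, 5, 5, 5),
               gB = c(0, 0, 0, 8, 9),   # three zeros -> excluded
               gC = c(0, 5, 6, 7, 8))   # median 6, one zero -> retained
  ribo <- rbind(gA = c(10, 10, 10, 10, 10),
                gB = c(4, 4, 4, 4, 4),
                gC = c(3, 3, 3, 3, 3))
  d <- make_paired(rna, ribo, rep("human", 5))
  te_lin <- compute_te(d$rna, d$ribo, d$samples, scale = "linear",
                       pseudocount = 0)
  expect_setequal(rownames(te_lin$te), c("gA", "gC"))
  expect_equal(unname(te_lin$te["gA", ]), rep(2, 5))
  expect_true("gB" %in% te_lin$filtered)
  te_log <- compute_te(d$rna, d$ribo, d$samples, scale = "log2",
                       pseudocount = 0)
  expect_equal(unname(te_log$te["gA", ]), rep(1, 5))

  # median zero triggers exclusion even with fewer than 3 zeros
  rna2 <- rbind(gA = c(0, 0, 5), gB = c(9, 9, 9))
  ribo2 <- rbind(gA = c(4, 4, 4), gB = c(2, 2, 2))
  d2 <- make_paired(rna2, ribo2, rep("human", 3))
  te2 <- compute_te(d2$rna, d2$ribo, d2$samples)
  expect_false("gA" %in% rownames(te2$te))

  # unpaired ribo sample errors
  bad <- d$samples[d$samples$sample_id != "p01_rna", ]
  expect_error(suppressWarnings(compute_te(d$rna, d$ribo, bad)), "pair")
})

test_that("te_var matches hand-evaluated decomposition", {
  # per-species mean log2 TE (0,0,0,0,2), zero within-species variance
  species <- rep(c("s1", "s2", "s3", "s4", "s5"), each = 2)
  vals <- matrix(rep(c(0, 0, 0, 0, 2), each = 2), nrow = 1,
                 dimnames = list("g1", sprintf("p%02d", 1:10)))
  te <- te_matrix(vals, species)
  res <- te_var(te)
  expect_equal(res$te_var, var(c(0, 0, 0, 0, 2)))
  expect_equal(res$te_var, 0.8)
  expect_equal(res$avg_sampling_variance, 0)

  # identical TE everywhere -> te_var exactly 0
  flat <- te_matrix(matrix(1.3, 2, 10, dimnames = list(c("a", "b"),
                                                       sprintf("p%02d", 1:10))),
                    species)
  expect_equal(te_var(flat)$te_var, c(0, 0))

  # decomposition identity holds exactly for random values
  set.seed(4)
  rnd <- matrix(rnorm(200), 20, 10,
                dimnames = list(paste0("g", 1:20), sprintf("p%02d", 1:10)))
  r <- te_var(te_matrix(rnd, species))
  expect_identical(r$te_var,
                   r$across_species_variance - r$avg_sampling_variance)
})

test_that("single-sample species are excluded from both terms", {
  species <- c("s1", "s1", "s2", "s2", "s3")
  vals <- matrix(c(0, 0, 1, 1, 50), 1,
                 dimnames = list("g", sprintf("p%02d", 1:5)))
  te <- te_matrix(vals, species)
  expect_message(res <- te_var(te), "single sample")
  expect_equal(res$n_species_used, 2L)
  expect_equal(res$te_var, var(c(0, 1)))  # s3 ignored entirely
  only_one <- te_matrix(vals[, 1:3, drop = FALSE], species[1:3])
  expect_error(suppressMessages(te_var(only_one)), ">= 2 species")
})

test_that("null te_var is centred at zero (simulation)", {
  set.seed(8)
  n_per <- 5L
  species <- rep(paste0("s", 1:5), each = n_per)
  sigma <- 0.6
  vals <- matrix(rnorm(10000 * length(species), 0, sigma), 10000,
                 dimnames = list(sprintf("g%05d", 1:10000),
                                 sprintf("p%02d", seq_along(species))))
  res <- te_var(te_matrix(vals, species))
  se <- sd(res$te_var) / sqrt(nrow(res))
  expect_lt(abs(mean(res$te_var)), 3 * se)
})

test_that("group_median follows its contract", {
  res <- data.frame(gene_id = c("a", "b", "c"),
                    te_var = c(0.1, 0.2, 0.9))
  class(res) <- c("TEVarResult", "data.frame")
  expect_equal(group_median(res, c("a", "b", "c")), 0.2)
  expect_equal(group_median(res, "a"), 0.1)
  expect_equal(group_median(res, c("a", "b", "c", "absent")), 0.2)
  expect_error(group_median(res, "zz"), "no genes")
})

test_that("resampling p-values behave at the extremes and under relabeling", {
  set.seed(21)
  species <- rep(paste0("s", 1:4), each = 4)
  base <- matrix(rnorm(50 * 16, 0, 0.3), 50, 16,
                 dimnames = list(sprintf("g%03d", 1:50),
                                 sprintf("p%02d", 1:16)))
  # plant an extreme group: species shifts much larger than noise
  shift <- rep(c(-6, -2, 2, 6), each = 4)
  base[1:10, ] <- base[1:10, ] + matrix(shift, 10, 16, byrow = TRUE)
  te <- te_matrix(base, species)
  gr <- list(planted = sprintf("g%03d", 1:10))
  res <- resample_group_pvalue(te, gr, iterations = 200, seed = 3)
  expect_equal(res$p_one_sided, 0)  # observed larger than all permutations

  # invariance to species relabeling
  relabel <- c(s1 = "x4", s2 = "x3", s3 = "x2", s4 = "x1")[species]
  res2 <- resample_group_pvalue(te_matrix(base, relabel), gr,
                                iterations = 200, seed = 3)
  expect_equal(res2$p_one_sided, res$p_one_sided)
  expect_equal(res2$observed_median, res$observed_median)

  expect_error(resample_group_pvalue(te, list(g = "nope"), 10, 1), "absent")
})

test_that("downsampling CI degenerates when k equals every species n", {
  set.seed(2)
  species <- rep(paste0("s", 1:3), each = 3)
  vals <- matrix(rnorm(20 * 9), 20, 9,
                 dimnames = list(paste0("g", 1:20), paste0("p", 1:9)))
  te <- te_matrix(vals, species)
  obs <- group_median(te_var(te), paste0("g", 1:5))
  ci <- downsample_group_ci(te, paste0("g", 1:5), k_samples = 3,
                            iterations = 50, seed = 1)
  expect_equal(as.vector(ci), c(obs, obs))
  ci2 <- downsample_group_ci(te, paste0("g", 1:5), k_samples = 2,
                             iterations = 200, seed = 1)
  expect_lte(ci2[["lower"]], ci2[["upper"]])
  expect_error(downsample_group_ci(te, paste0("g", 1:5), 4, 10, 1),
               "exceeds")
})

test_that("doubling all Ribo counts leaves te_var unchanged", {
  cfg <- sim_config(n_genes = 150L, n_species = 3L,
                    samples_per_species = c(4L, 4L, 4L), seed = 13L)
  sim <- simulate_counts(cfg)
  norm <- function(cm) normalize_counts(length_adjust(cm))
  te1 <- compute_te(norm(sim$rna), norm(sim$ribo), sim$samples,
                    pseudocount = 0)
  doubled <- CountMatrix(sim$ribo$counts * 2, sim$ribo$feature_lengths)
  te2 <- compute_te(norm(sim$rna), norm(doubled), sim$samples,
                    pseudocount = 0)
  # joint renormalization absorbs the common factor: log2 TE shifts by a
  # gene-independent constant (here exactly 0), te_var is unchanged
  expect_equal(te_var(te2)$te_var, te_var(te1)$te_var, tolerance = 1e-9)
})
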