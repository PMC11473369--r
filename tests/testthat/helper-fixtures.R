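# Shared fixtures built in code. Simulations here are kept small; the
# full-size generator settings are exercised in test-acceptance.R.

# paired two-species design with planted regulation modes (4-fold effects)
make_regulation_sim <- function(seed = 11L, n_background = 200L,
                                n_per_mode = 20L) {
  cfg <- sim_config(
    n_species = 2L, samples_per_species = c(10L, 10L),
    n_genes = n_background + 3L * n_per_mode,
    sigma_between = 0.1, sigma_within = 0.2,
    planted_regulation = list(
      buffering = list(n_genes = n_per_mode, rna_log2fc = -2, te_log2fc = 2),
      exclusive = list(n_genes = n_per_mode, rna_log2fc = 0, te_log2fc = 2),
      intensified = list(n_genes = n_per_mode, rna_log2fc = 2, te_log2fc = 2)),
    seed = seed)
  sim <- simulate_counts(cfg)
  rna <- normalize_counts(length_adjust(sim$rna))
  ribo <- normalize_counts(length_adjust(sim$ribo))
  list(sim = sim, rna = rna, ribo = ribo,
       te = compute_te(rna, ribo, sim$samples))
}

# TE matrix with exact, hand-chosen values (no counts involved)
make_te_fixture <- function(values, species) {
  te_matrix(values, species, scale = "log2")
}

# independent brute-force tau oracle: literal formula evaluation
tau_oracle <- function(x) {
  xhat <- x / max(x)
  sum(1 - xhat) / (length(x) - 1)
}

# independent brute-force ORF collapse oracle: pairwise in-frame overlap
# plus transitive closure by repeated sweeps
collapse_oracle <- function(orfs, overlap = 0.9) {
  n <- nrow(orfs)
  pos <- lapply(seq_len(n), function(i) {
    p <- seq.int(orfs$start[i], orfs$end[i] - 1L)
    if (orfs$strand[i] == "-") p <- rev(p)
    list(pos = p, phase = (seq_along(p) - 1L) %% 3L)
  })
  adj <- diag(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || orfs$chrom[i] != orfs$chrom[j] ||
          orfs$strand[i] != orfs$strand[j]) next
      shared <- 0L
      for (k in seq_along(pos[[i]]$pos)) {
        m <- which(pos[[j]]$pos == pos[[i]]$pos[k])
        if (length(m) && pos[[j]]$phase[m] == pos[[i]]$phase[k]) {
          shared <- shared + 1L
        }
      }
      if (shared / min(length(pos[[i]]$pos), length(pos[[j]]$pos)) >=
          overlap) {
        adj[i, j] <- TRUE
      }
    }
  }
  reach <- adj
  for (rep in seq_len(n)) reach <- (reach %*% reach) > 0
  groups <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (groups[i] == 0L) {
      g <- g + 1L
      groups[which(reach[i, ] | reach[, i])] <- g
    }
  }
  groups
}

# structure-call pipeline on toy genome output: counterpart intact
# fractions measured by re-translating the emitted sequences
toy_fractions <- function(toy) {
  do.call(rbind, lapply(seq_len(nrow(toy$counterparts)), function(i) {
    cp <- toy$counterparts[i, ]
    orf <- toy$orfs[toy$orfs$orf_id == cp$feature_id, ]
    orf_seq <- substring(toy$sequences[[orf$species]], orf$start + 1, orf$end)
    data.frame(orf_id = cp$feature_id, target_species = cp$target_species,
               intact_fraction = inframe_intact_fraction(orf_seq,
                                                         cp$counterpart_seq),
               stringsAsFactors = FALSE)
  }))
}
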