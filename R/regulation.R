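#' Differential expression stand-in test
#'
#' A lightweight two-group test used where the original workflow would run
#' a negative-binomial GLM: per-gene Welch t-test on `log2(normalized + 1)`
#' with Benjamini-Hochberg adjustment. The output schema (`feature_id`,
#' `log2_fold_change`, `adjusted_p`, `significant`) is the package's
#' differential-expression contract, so externally produced tables (e.g.
#' from DESeq2) can be substituted anywhere a `DETable` is accepted.
#'
#' Significance requires both an absolute fold change of at least
#' `fc_cutoff` and an adjusted p below `alpha`. Genes with zero variance
#' in both groups get p = 1.
#'
#' @param norm a `NormalizedMatrix`.
#' @param group_a,group_b sample ids of the two groups (>= 2 each); the
#'   fold change is A minus B on the log2 scale.
#' @param contrast label stored in the result.
#' @param fc_cutoff minimum absolute linear fold change (default 1.5).
#' @param alpha adjusted-p cutoff (default 0.05).
#' @return A `DETable` data.frame: `feature_id`, `contrast`,
#'   `log2_fold_change`, `adjusted_p`, `significant`.
#' @export
standin_de_test <- function(norm, group_a, group_b, contrast = "A_vs_B",
                            fc_cutoff = 1.5, alpha = 0.05) {
  stopifnot(is(norm, "NormalizedMatrix"))
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("need >= 2 samples per group")
  }
  a <- log2(norm$values[, group_a, drop = FALSE] + 1)
  b <- log2(norm$values[, group_b, drop = FALSE] + 1)
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- 2 * pt(abs(tstat), df, lower.tail = FALSE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    message(sum(degenerate), " gene(s) with zero variance in both groups; p set to 1")
    p[degenerate] <- 1
  }
  padj <- p.adjust(p, method = "BH")
  lfc <- ma - mb
  data.frame(feature_id = rownames(norm$values),
             contrast = contrast,
             log2_fold_change = lfc,
             adjusted_p = padj,
             significant = abs(lfc) >= log2(fc_cutoff) & padj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Species-specific TE shift test
#'
#' Contrasts one focal species' log2 TE against all other species pooled.
#' The effect is the difference of group means; significance comes from a
#' permutation test that shuffles the species labels over sample pairs
#' (add-one corrected, two-sided), followed by Benjamini-Hochberg
#' adjustment. This is a documented stand-in for an interaction-term GLM;
#' an imported interaction DE table in the `DETable` schema can be used
#' instead.
#'
#' @param te a `TEMatrix` on the log2 scale.
#' @param focal_species species label to contrast against the rest.
#' @param iterations permutations (default 2000).
#' @param seed integer seed.
#' @param fc_cutoff,alpha significance thresholds as in
#'   [standin_de_test()].
#' @return A `DETable` data.frame (contrast `"<focal>_vs_rest"`).
#' @export
te_species_test <- function(te, focal_species, iterations = 2000L,
                            seed = 1L, fc_cutoff = 1.5, alpha = 0.05) {
  stopifnot(is(te, "TEMatrix"))
  if (te$scale != "log2") stop("te_species_test expects a log2-scale TEMatrix")
  is_focal <- te$pairs$species == focal_species
  n_f <- sum(is_focal); n_o <- sum(!is_focal)
  if (n_f < 2L) stop("need >= 2 sample pairs for the focal species")
  if (n_o < 1L) stop("need at least one non-focal sample pair")

  w_obs <- ifelse(is_focal, 1 / n_f, -1 / n_o)
  effect <- drop(te$te %*% w_obs)

  set.seed(seed)
  n <- length(is_focal)
  W <- vapply(seq_len(iterations), function(i) {
    perm <- sample.int(n, n_f)
    w <- rep(-1 / n_o, n)
    w[perm] <- 1 / n_f
    w
  }, numeric(n))
  perm_eff <- abs(te$te %*% W)
  exceed <- rowSums(perm_eff >= abs(effect))
  p <- (1 + exceed) / (1 + iterations)
  padj <- p.adjust(p, method = "BH")
  data.frame(feature_id = rownames(te$te),
             contrast = paste0(focal_species, "_vs_rest"),
             log2_fold_change = effect,
             adjusted_p = padj,
             significant = abs(effect) >= log2(fc_cutoff) & padj < alpha,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Classify the regulatory mode of species-specific TE changes
#'
#' For genes with a significant TE change in the focal species:
#' * RNA significant and RNA/TE fold changes in opposite directions ->
#'   **buffering** (translation compensates a transcript-abundance shift);
#' * RNA significant, same direction -> **intensified**;
#' * RNA not significant -> **exclusive** (regulation only visible at the
#'   Ribo-seq level).
#' Genes without a significant TE change get mode `"none"`. The sign of a
#' non-significant fold change is never used. The three modes partition
#' the TE-significant set exactly.
#'
#' @param rna,ribo,te `DETable` data.frames for the same focal-species
#'   contrast (RNA abundance, Ribo-seq occupancy, TE).
#' @param focal_species label recorded in the output.
#' @return A `RegulationCall` data.frame: `gene_id`, `focal_species`,
#'   `rna_lfc`, `rna_sig`, `ribo_lfc`, `ribo_sig`, `te_lfc`, `te_sig`,
#'   `mode`.
#' @export
classify_mode <- function(rna, ribo, te, focal_species = NA_character_) {
  genes <- te$feature_id
  i_rna <- match(genes, rna$feature_id)
  i_ribo <- match(genes, ribo$feature_id)
  missing <- is.na(i_rna) | is.na(i_ribo)
  if (any(missing)) {
    warning(sum(missing), " gene(s) missing from the RNA or Ribo table; ",
            "mode set to 'none'")
  }
  out <- data.frame(gene_id = genes,
                    focal_species = focal_species,
                    rna_lfc = rna$log2_fold_change[i_rna],
                    rna_sig = rna$significant[i_rna],
                    ribo_lfc = ribo$log2_fold_change[i_ribo],
                    ribo_sig = ribo$significant[i_ribo],
                    te_lfc = te$log2_fold_change,
                    te_sig = te$significant,
                    stringsAsFactors = FALSE, row.names = NULL)
  mode <- rep("none", nrow(out))
  callable <- out$te_sig & !missing
  opposite <- callable & out$rna_sig & sign(out$rna_lfc) != sign(out$te_lfc)
  same <- callable & out$rna_sig & sign(out$rna_lfc) == sign(out$te_lfc)
  alone <- callable & !out$rna_sig
  mode[opposite] <- "buffering"
  mode[same] <- "intensified"
  mode[alone] <- "exclusive"
  out$mode <- mode
  out
}

#' Developmental directionality of differential features
#'
#' Contrasts are oriented so that a positive fold change means higher in
#' the adult/postnatal state. A feature significantly up in the fetal-like
#' state in at least one contrast (and never postnatal) is `"prenatal"`;
#' the converse is `"postnatal"`; significant in both directions across
#' the supplied contrasts is `"both"`; otherwise `"none"`.
#'
#' @param de_cm_vs_lv a `DETable` (e.g. iPSC-CM vs adult LV).
#' @param de_other optional second `DETable` with the same orientation
#'   (e.g. an external prenatal vs postnatal contrast).
#' @return data.frame with `feature_id` and `stage` in
#'   `{"prenatal", "postnatal", "both", "none"}`.
#' @export
classify_developmental <- function(de_cm_vs_lv, de_other = NULL) {
  tables <- list(de_cm_vs_lv)
  if (!is.null(de_other)) tables <- c(tables, list(de_other))
  genes <- unique(unlist(lapply(tables, `[[`, "feature_id")))
  up <- down <- setNames(rep(FALSE, length(genes)), genes)
  for (tab in tables) {
    sig <- tab[tab$significant, , drop = FALSE]
    up[sig$feature_id[sig$log2_fold_change > 0]] <- TRUE
    down[sig$feature_id[sig$log2_fold_change < 0]] <- TRUE
  }
  stage <- rep("none", length(genes))
  stage[down & !up] <- "prenatal"
  stage[up & !down] <- "postnatal"
  stage[up & down] <- "both"
  data.frame(feature_id = genes, stage = stage,
             stringsAsFactors = FALSE, row.names = NULL)
}
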