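#' Actively transcribed genes per species
#'
#' A gene is active in a species when its mean FPKM across that species'
#' replicates is at least `fpkm_mean_min` and at least `min_reps`
#' replicates reach `fpkm_min_rep`. For pseudogenes and unannotated genes
#' the caller should supply an FPKM matrix built from uniquely mapped
#' reads only.
#'
#' @param fpkm_mat numeric FPKM matrix (genes x samples).
#' @param samples a [SampleTable()]; only RNA-assay samples present in
#'   `fpkm_mat` are used.
#' @param fpkm_mean_min,fpkm_min_rep,min_reps filter thresholds (defaults
#'   1.0, 0.5, 3).
#' @return Named list: per species, the character vector of active genes.
#' @export
active_genes <- function(fpkm_mat, samples, fpkm_mean_min = 1.0,
                         fpkm_min_rep = 0.5, min_reps = 3L) {
  samples <- as.data.frame(samples)
  rna <- samples[samples$assay == "RNA" &
                   samples$sample_id %in% colnames(fpkm_mat), , drop = FALSE]
  if (!nrow(rna)) stop("no RNA samples found in the FPKM matrix")
  out <- list()
  for (sp in unique(rna$species)) {
    cols <- rna$sample_id[rna$species == sp]
    if (length(cols) < min_reps) {
      stop("species '", sp, "' has ", length(cols), " replicates; the ",
           "min_reps = ", min_reps, " filter is unsatisfiable (override ",
           "min_reps to proceed)")
    }
    m <- fpkm_mat[, cols, drop = FALSE]
    keep <- rowMeans(m) >= fpkm_mean_min &
      rowSums(m >= fpkm_min_rep) >= min_reps
    out[[sp]] <- rownames(fpkm_mat)[keep]
  }
  out
}

#' Replicated ORFs with active host genes
#'
#' @param orfs ORF table (data.frame) with columns `orf_id`, `host_gene`,
#'   `species`, `n_samples_predicted`.
#' @param active named list of active gene sets per species (from
#'   [active_genes()]).
#' @param min_samples minimum samples an ORF must be predicted in
#'   (default 3).
#' @return The subset of `orfs` passing both filters.
#' @export
replicated_orfs <- function(orfs, active, min_samples = 3L) {
  keep <- orfs$n_samples_predicted >= min_samples &
    mapply(function(g, sp) g %in% (active[[sp]] %||% character()),
           orfs$host_gene, orfs$species)
  orfs[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# genomic positions of an ORF in translation order, with reading-frame
# phase 0/1/2 attached; blocks is a two-column matrix of 0-based
# half-open [start, end) intervals
.orf_positions <- function(start, end, strand, blocks = NULL) {
  if (is.null(blocks)) blocks <- cbind(start, end)
  blocks <- blocks[order(blocks[, 1]), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(blocks)), function(i) {
    seq.int(blocks[i, 1], blocks[i, 2] - 1L)
  }), use.names = FALSE)
  if (strand == "-") pos <- rev(pos)
  data.frame(pos = pos, phase = (seq_along(pos) - 1L) %% 3L)
}

#' Collapse redundant ORF isoforms
#'
#' ORFs on the same chromosome and strand are grouped when they share at
#' least `overlap` of the shorter ORF's length in in-frame genomic
#' positions (positions covered by both ORFs with the same reading-frame
#' phase). Groups are the transitive closure of pairwise matches. Within a
#' group the representative is chosen by: cognate (AUG) start first, then
#' longest, then lexicographically smallest `orf_id`. Pairs overlapping in
#' different frames are never merged.
#'
#' @param orfs data.frame with `orf_id`, `chrom`, `start`, `end`,
#'   `strand`, `start_codon`, `length_codons`; optional list-column
#'   `blocks` of 0-based half-open interval matrices for spliced ORFs.
#' @param overlap collapse threshold on the shorter ORF (default 0.9).
#' @return data.frame with `orf_id`, `group` (integer), `representative`
#'   (orf_id of the group representative), `is_representative`.
#' @export
collapse_orfs <- function(orfs, overlap = 0.9) {
  n <- nrow(orfs)
  has_blocks <- "blocks" %in% names(orfs)
  posn <- lapply(seq_len(n), function(i) {
    .orf_positions(orfs$start[i], orfs$end[i], orfs$strand[i],
                   if (has_blocks) orfs$blocks[[i]] else NULL)
  })
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (orfs$chrom[i] != orfs$chrom[j] ||
          orfs$strand[i] != orfs$strand[j]) next
      pi <- posn[[i]]; pj <- posn[[j]]
      m <- match(pi$pos, pj$pos)
      covered <- !is.na(m)
      if (!any(covered)) next
      inframe <- sum(pi$phase[covered] == pj$phase[m[covered]])
      if (inframe == 0 && sum(covered) > 0) next  # different frame: never merge
      frac <- inframe / min(nrow(pi), nrow(pj))
      if (frac >= overlap) parent[find(i)] <- find(j)
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  group <- match(root, unique(root))
  cognate <- toupper(orfs$start_codon) %in% c("ATG", "AUG")
  rep_of <- vapply(unique(group), function(g) {
    members <- which(group == g)
    ord <- order(-cognate[members], -orfs$length_codons[members],
                 orfs$orf_id[members])
    orfs$orf_id[members[ord[1]]]
  }, character(1))
  data.frame(orf_id = orfs$orf_id, group = group,
             representative = rep_of[group],
             is_representative = orfs$orf_id == rep_of[group],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Combine mapping, BLAST and activity evidence per feature and species
#'
#' For every (feature, target species) pair, summarizes: the liftover-style
#' mapping status (`unique_full` when the feature maps fully to a single
#' counterpart region on one strand and chromosome, `partial_or_multiple`
#' otherwise, `none` without a mapping row); the best BLAST E-value to a
#' feature of the target species; the target feature with the longest
#' overlap to the mapped counterpart region; and whether a homolog is
#' found through either channel. A homolog exists when the mapping is
#' `unique_full` and overlaps a target-universe feature, or when the best
#' E-value is at most `evalue_max`; the search universe is all features in
#' `target_features` (all transcribed genes / all predicted ORFs per
#' species).
#'
#' @param features data.frame of query features: `feature_id`, `species`.
#' @param species_list all species analyzed.
#' @param mapping data.frame with `feature_id`, `source_species`,
#'   `target_species`, `target_chrom`, `target_start`, `target_end`,
#'   `target_strand`, `colinear_flag`.
#' @param hits BLAST tabular hits (from [read_hits()]); `qseqid` must be a
#'   feature id and `sseqid` a feature id present in `target_features`.
#' @param target_features data.frame of candidate homologs across species:
#'   `feature_id`, `species`, `chrom`, `start`, `end`, `strand`,
#'   `transcribed` (logical), `translated` (logical).
#' @param counterpart_reads optional data.frame with `feature_id`,
#'   `target_species`, `pooled_reads` (pooled Ribo-seq reads over the
#'   counterpart region); missing pairs default to 0.
#' @param evalue_max BLAST acceptance cutoff (default 1e-4).
#' @return `HomologyEvidence` data.frame with one row per (feature,
#'   target species): `feature_id`, `species`, `target_species`,
#'   `liftover_status`, `blast_best_evalue`, `target_feature`,
#'   `target_transcribed`, `target_translated`, `counterpart_reads`,
#'   `homolog_found`.
#' @export
resolve_homologs <- function(features, species_list, mapping, hits,
                             target_features, counterpart_reads = NULL,
                             evalue_max = 1e-4) {
  known <- unique(c(species_list, features$species))
  bad <- setdiff(unique(mapping$target_species), known)
  if (length(bad)) {
    stop("mapping table references unknown species: ",
         paste(bad, collapse = ", "))
  }
  rows <- list()
  for (i in seq_len(nrow(features))) {
    fid <- features$feature_id[i]
    fsp <- features$species[i]
    for (tsp in setdiff(species_list, fsp)) {
      map_rows <- mapping[mapping$feature_id == fid &
                            mapping$target_species == tsp, , drop = FALSE]
      status <- if (nrow(map_rows) == 0) {
        "none"
      } else if (nrow(map_rows) == 1 && isTRUE(as.logical(map_rows$colinear_flag))) {
        "unique_full"
      } else {
        "partial_or_multiple"
      }

      tf <- target_features[target_features$species == tsp, , drop = FALSE]
      target_feature <- NA_character_
      if (status == "unique_full" && nrow(tf)) {
        ov <- pmin(tf$end, map_rows$target_end) -
          pmax(tf$start, map_rows$target_start)
        ov[tf$chrom != map_rows$target_chrom |
             tf$strand != map_rows$target_strand] <- 0
        if (any(ov > 0)) {
          target_feature <- tf$feature_id[which.max(ov)]
        }
      }

      h <- hits[hits$qseqid == fid & hits$sseqid %in% tf$feature_id, ,
                drop = FALSE]
      best_e <- if (nrow(h)) min(h$evalue) else NA_real_
      blast_target <- if (nrow(h)) h$sseqid[which.min(h$evalue)] else NA_character_
      if (is.na(target_feature) && !is.na(best_e) && best_e <= evalue_max) {
        target_feature <- blast_target
      }

      lift_hom <- status == "unique_full" && !is.na(target_feature)
      blast_hom <- !is.na(best_e) && best_e <= evalue_max
      found <- lift_hom || blast_hom

      trn <- tln <- NA
      if (!is.na(target_feature)) {
        k <- match(target_feature, tf$feature_id)
        trn <- isTRUE(as.logical(tf$transcribed[k]))
        tln <- isTRUE(as.logical(tf$translated[k]))
      }

      reads <- 0
      if (!is.null(counterpart_reads)) {
        r <- counterpart_reads[counterpart_reads$feature_id == fid &
                                 counterpart_reads$target_species == tsp, ,
                               drop = FALSE]
        if (nrow(r)) reads <- sum(r$pooled_reads)
      }

      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = fid, species = fsp, target_species = tsp,
        liftover_status = status, blast_best_evalue = best_e,
        target_feature = target_feature,
        target_transcribed = trn, target_translated = tln,
        counterpart_reads = reads, homolog_found = found,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Evolutionary age of genes
#'
#' A gene with no homolog detected in any other species is
#' `species_specific`. A gene of a hominini species whose detected,
#' transcribed homologs are confined to the other hominini species is
#' `hominini_specific`. Everything else is `preserved`.
#'
#' @param evidence `HomologyEvidence` from [resolve_homologs()].
#' @param hominini the two hominini species labels
#'   (default `c("human", "chimp")`).
#' @return `AgeCall` data.frame: `feature_id`, `species`, `age`.
#' @export
assign_gene_age <- function(evidence, hominini = c("human", "chimp")) {
  .assign_age(evidence, hominini, activity_col = "target_transcribed",
              use_reads = FALSE, min_counterpart_reads = Inf)
}

#' Evolutionary age of sORFs
#'
#' As [assign_gene_age()], keyed on translated homologs, with the extra
#' requirement that a young call (species-specific or hominini-specific)
#' needs fewer than `min_counterpart_reads` pooled Ribo-seq reads in every
#' counterpart region outside the young lineage; a counterpart at or above
#' the cutoff is evidence of translation and forces `preserved`.
#'
#' @inheritParams assign_gene_age
#' @param min_counterpart_reads pooled-read cutoff (default 10).
#' @return `AgeCall` data.frame: `feature_id`, `species`, `age`.
#' @export
assign_orf_age <- function(evidence, hominini = c("human", "chimp"),
                           min_counterpart_reads = 10L) {
  .assign_age(evidence, hominini, activity_col = "target_translated",
              use_reads = TRUE,
              min_counterpart_reads = min_counterpart_reads)
}

.assign_age <- function(evidence, hominini, activity_col, use_reads,
                        min_counterpart_reads) {
  split_ev <- split(evidence, evidence$feature_id)
  rows <- lapply(split_ev, function(ev) {
    fsp <- ev$species[1]
    active_hom <- ev$homolog_found & !is.na(ev[[activity_col]]) &
      ev[[activity_col]]
    hom_sp <- ev$target_species[active_hom]
    # read evidence in a counterpart without a detected active homolog
    # disqualifies a young call (translation presence of unclear identity);
    # species with an active homolog are judged by the homolog instead
    reads_ok <- if (use_reads) {
      all(ev$counterpart_reads[!active_hom] < min_counterpart_reads)
    } else TRUE
    age <- if (length(hom_sp) == 0 && reads_ok) {
      "species_specific"
    } else if (fsp %in% hominini && length(hom_sp) > 0 &&
               all(hom_sp %in% hominini) && reads_ok) {
      "hominini_specific"
    } else {
      "preserved"
    }
    data.frame(feature_id = ev$feature_id[1], species = fsp, age = age,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' In-frame intact fraction of a counterpart sequence
#'
#' Walks the counterpart sequence in the ORF's reading frame from the
#' aligned start and reports the fraction of the ORF's codons preceding
#' the first disrupting event: an in-frame stop codon, an accumulated
#' alignment-gap length that is not a multiple of 3 (a frameshift; no
#' frame-restoration scanning is attempted), or the end of the counterpart
#' sequence. A full-length, stop-free walk returns 1.0.
#'
#' @param orf_seq ORF nucleotide sequence (may contain `-` when an aligned
#'   string is supplied); if its final codon is a stop it is not counted
#'   in the ORF's codon length.
#' @param counterpart_seq counterpart nucleotide sequence aligned to
#'   `orf_seq` (equal string length, `-` for gaps) or a gapless sequence
#'   taken as aligned from the ORF start.
#' @param length_codons optional translated ORF length in codons
#'   (stop excluded); derived from `orf_seq` when missing.
#' @return Intact fraction in \[0, 1\].
#' @export
inframe_intact_fraction <- function(orf_seq, counterpart_seq,
                                    length_codons = NULL) {
  orf_seq <- toupper(chartr("U", "T", orf_seq))
  counterpart_seq <- toupper(chartr("U", "T", counterpart_seq))
  o <- strsplit(orf_seq, "")[[1]]
  c_aln <- strsplit(counterpart_seq, "")[[1]]
  if (length(o) != length(c_aln)) {
    if (any(o == "-") || any(c_aln == "-")) {
      stop("aligned sequences must have equal length")
    }
    # gapless counterpart: identity alignment from the ORF start
    n <- max(length(o), length(c_aln))
    o <- c(o, rep("-", n - length(o)))
    c_aln <- c(c_aln, rep("-", n - length(c_aln)))
  }
  stops <- c("TAA", "TAG", "TGA")
  orf_bases <- sum(o != "-")
  if (is.null(length_codons)) {
    length_codons <- orf_bases %/% 3
    degap_o <- paste(o[o != "-"], collapse = "")
    last <- substr(degap_o, 3 * length_codons - 2, 3 * length_codons)
    if (length_codons > 0 && last %in% stops) {
      length_codons <- length_codons - 1L
    }
  }
  if (length_codons < 1) stop("ORF must contain at least one codon")

  # counterpart bases consumed before each ORF base (in alignment order);
  # the extra final entry covers the end of the last ORF base
  orf_base_cols <- which(o != "-")
  cp_nongap <- cumsum(c_aln != "-")
  cp_before <- c(cp_nongap[orf_base_cols] - (c_aln[orf_base_cols] != "-"),
                 cp_nongap[orf_base_cols[orf_bases]])
  degap_c <- paste(c_aln[c_aln != "-"], collapse = "")
  n_c <- nchar(degap_c)

  for (i in seq_len(length_codons)) {
    ci <- cp_before[3 * (i - 1) + 1]
    ci_end <- cp_before[min(3 * i + 1, orf_bases + 1L)]
    if ((ci - 3 * (i - 1)) %% 3 != 0) {
      return((i - 1) / length_codons)   # frame already broken
    }
    if ((ci_end - 3 * i) %% 3 != 0) {
      return((i - 1) / length_codons)   # frameshifting gap inside this codon
    }
    if (ci + 3 > n_c) return((i - 1) / length_codons)  # counterpart ends
    codon <- substr(degap_c, ci + 1, ci + 3)
    if (codon %in% stops) return((i - 1) / length_codons)
  }
  1.0
}

#' Structural class of young sORFs
#'
#' Young sORFs whose encoding region has no aligned counterpart in any
#' analyzed species are `orphan`. Young sORFs whose aligned counterparts
#' are truncated by at least `truncation_cutoff` of the in-frame sequence
#' (intact fraction at most `1 - truncation_cutoff`) in all aligned
#' species (`rule = "all"`, default) or in at least one (`rule = "any"`)
#' are `de_novo`; the rest are `intact`. Only young ORFs are classified;
#' preserved ORFs receive no structure call.
#'
#' @param orf_ids ids of young ORFs to classify.
#' @param fractions data.frame with `orf_id`, `target_species`,
#'   `intact_fraction` (one row per aligned counterpart; unaligned species
#'   are simply absent or have `NA`).
#' @param truncation_cutoff minimum truncated fraction for a de novo call
#'   (default 0.7).
#' @param rule `"all"` or `"any"` aligned species must satisfy the
#'   truncation rule.
#' @return `StructureCall` data.frame: `orf_id`, `n_aligned`, `structure`.
#' @export
classify_structure <- function(orf_ids, fractions,
                               truncation_cutoff = 0.7,
                               rule = c("all", "any")) {
  rule <- match.arg(rule)
  out <- lapply(orf_ids, function(id) {
    fr <- fractions$intact_fraction[fractions$orf_id == id]
    fr <- fr[!is.na(fr)]
    structure_class <- if (!length(fr)) {
      "orphan"
    } else {
      truncated <- fr <= 1 - truncation_cutoff
      if ((rule == "all" && all(truncated)) ||
          (rule == "any" && any(truncated))) "de_novo" else "intact"
    }
    data.frame(orf_id = id, n_aligned = length(fr),
               structure = structure_class, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
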