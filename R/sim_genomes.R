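#' Specification of a toy multi-species genome set
#'
#' Describes a set of single-chromosome genomes in which features with
#' known evolutionary history are planted: orthologous genes present in
#' every species, young genes present only in the focal species or in the
#' hominini pair, and small ORFs whose counterpart regions in the other
#' species are intact, truncated (de novo) or absent (orphan). The focal
#' species is the first in `species`.
#'
#' @param species species labels (default the five-species heart design);
#'   the first two are treated as the hominini pair.
#' @param chrom_length shared chromosome length (nt) before the
#'   focal-specific tail that hosts orphan ORFs.
#' @param n_ortholog genes planted colinearly in every species.
#' @param n_species_specific focal-species-only genes.
#' @param n_hominini genes present in the first two species only.
#' @param n_sorf_intact,n_sorf_denovo,n_sorf_orphan young focal sORFs with
#'   each counterpart structure.
#' @param n_sorf_hominini young sORFs translated in both hominini species
#'   (intact counterparts elsewhere, below the read cutoff).
#' @param n_sorf_preserved sORFs with translated counterparts everywhere
#'   (pooled counterpart reads above the cutoff).
#' @param gene_length planted gene length (nt).
#' @param sorf_codons translated sORF length in codons (stop excluded).
#' @param denovo_truncation truncated fraction(s) planted into de novo
#'   counterparts, recycled over the de novo sORFs; each must be >= 0.7.
#' @param feature_spacing gap between planted features (nt).
#' @return Validated list of class `ToyGenomeSpec`.
#' @export
toy_genome_spec <- function(species = .default_species,
                            chrom_length = 60000L,
                            n_ortholog = 10L,
                            n_species_specific = 5L,
                            n_hominini = 5L,
                            n_sorf_intact = 5L,
                            n_sorf_denovo = 5L,
                            n_sorf_orphan = 5L,
                            n_sorf_hominini = 3L,
                            n_sorf_preserved = 3L,
                            gene_length = 600L,
                            sorf_codons = 40L,
                            denovo_truncation = 0.8,
                            feature_spacing = 50L) {
  if (length(species) < 3) stop("need >= 3 species (hominini pair + outgroup)")
  if (any(denovo_truncation < 0.7)) {
    stop("planted de novo truncation fractions must be >= 0.7")
  }
  if (sorf_codons < 10) stop("sorf_codons must be >= 10")
  n_feat <- n_ortholog + n_species_specific + n_hominini + n_sorf_intact +
    n_sorf_denovo + n_sorf_hominini + n_sorf_preserved
  sorf_span <- 3L * (sorf_codons + 1L)
  body_needed <- n_feat * (gene_length + feature_spacing) + feature_spacing
  if (body_needed > chrom_length) {
    stop("planted features would overlap or exceed the sequence length; ",
         "increase chrom_length (need >= ", body_needed, ")")
  }
  structure(list(species = species, chrom_length = as.integer(chrom_length),
                 n_ortholog = n_ortholog,
                 n_species_specific = n_species_specific,
                 n_hominini = n_hominini,
                 n_sorf_intact = n_sorf_intact,
                 n_sorf_denovo = n_sorf_denovo,
                 n_sorf_orphan = n_sorf_orphan,
                 n_sorf_hominini = n_sorf_hominini,
                 n_sorf_preserved = n_sorf_preserved,
                 gene_length = as.integer(gene_length),
                 sorf_codons = as.integer(sorf_codons),
                 sorf_span = sorf_span,
                 denovo_truncation = denovo_truncation,
                 feature_spacing = as.integer(feature_spacing)),
            class = "ToyGenomeSpec")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# stop-free random ORF: ATG + (codons - 1) non-stop codons + TAA
.random_orf <- function(codons) {
  stops <- c("TAA", "TAG", "TGA")
  pool <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            c("A", "C", "G", "T")), 1, paste, collapse = "")
  pool <- setdiff(pool, stops)
  body <- sample(pool, codons - 1, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

.splice_seq <- function(seq, start, replacement) {
  # start is 0-based; replacement overwrites in place
  paste0(substr(seq, 1, start),
         replacement,
         substr(seq, start + nchar(replacement) + 1, nchar(seq)))
}

#' Simulate toy genomes with planted evolutionary history
#'
#' Generates one random chromosome per species, plants the features
#' described by the [toy_genome_spec()] and emits every evidence table the
#' evolutionary classification consumes, together with the ground truth.
#' Orthologous features are colinear across species with reciprocal
#' BLAST-style hits (E = 1e-30); young features have no mapping or hit
#' rows in the species they are absent from; de novo sORF counterparts
#' carry an engineered premature stop so the in-frame intact fraction
#' equals `1 - truncation` exactly (to the codon); orphan sORFs live in a
#' focal-specific tail beyond the other species' sequence ends.
#'
#' @param spec a [toy_genome_spec()].
#' @param seed integer seed.
#' @return List with: `sequences` (named character vector per species,
#'   one chromosome `chr1`), `genes` and `orfs` (focal feature tables),
#'   `target_features` (the homolog search universe across all species),
#'   `mapping`, `hits` (BLAST outfmt-6 columns), `counterparts`
#'   (`feature_id`, `target_species`, `pooled_reads`, `counterpart_seq`),
#'   and `truth` (planted age, structure and truncation per feature).
#' @export
simulate_toy_genomes <- function(spec, seed = 1L) {
  stopifnot(is(spec, "ToyGenomeSpec"))
  set.seed(seed)
  species <- spec$species
  focal <- species[1]
  hominini <- species[1:2]
  L <- spec$chrom_length
  tail_len <- spec$n_sorf_orphan * (spec$sorf_span + spec$feature_spacing) +
    spec$feature_spacing

  seqs <- setNames(vapply(species, function(s) .random_dna(L), character(1)),
                   species)
  seqs[focal] <- paste0(seqs[focal], .random_dna(tail_len))

  feat_defs <- c(
    rep("ortholog", spec$n_ortholog),
    rep("species_specific_gene", spec$n_species_specific),
    rep("hominini_gene", spec$n_hominini),
    rep("sorf_intact", spec$n_sorf_intact),
    rep("sorf_denovo", spec$n_sorf_denovo),
    rep("sorf_hominini", spec$n_sorf_hominini),
    rep("sorf_preserved", spec$n_sorf_preserved))
  trunc_vals <- rep_len(spec$denovo_truncation, spec$n_sorf_denovo)

  genes <- list(); orfs <- list(); universe <- list()
  mapping <- list(); hits <- list(); counterparts <- list(); truth <- list()
  pos <- spec$feature_spacing
  i_denovo <- 0L

  add_hit <- function(q, s, len, evalue = 1e-30) {
    hits[[length(hits) + 1L]] <<- data.frame(
      qseqid = q, sseqid = s, pident = 100, length = len, mismatch = 0,
      gapopen = 0, qstart = 1, qend = len, sstart = 1, send = len,
      evalue = evalue, bitscore = 2 * len, stringsAsFactors = FALSE)
  }
  add_map <- function(fid, tsp, start, end) {
    mapping[[length(mapping) + 1L]] <<- data.frame(
      feature_id = fid, source_species = focal, target_species = tsp,
      target_chrom = "chr1", target_start = start, target_end = end,
      target_strand = "+", colinear_flag = TRUE, stringsAsFactors = FALSE)
  }

  for (i in seq_along(feat_defs)) {
    kind <- feat_defs[i]
    is_sorf <- startsWith(kind, "sorf")
    flen <- if (is_sorf) spec$sorf_span else spec$gene_length
    start <- pos; end <- pos + flen
    pos <- end + spec$feature_spacing
    fid <- sprintf("%s_%03d", kind, i)

    if (!is_sorf) {
      present <- switch(kind,
        ortholog = species,
        species_specific_gene = focal,
        hominini_gene = hominini)
      gene_seq <- .random_dna(flen)
      for (sp in present) {
        seqs[sp] <- .splice_seq(seqs[sp], start, gene_seq)
        inst <- if (sp == focal) fid else paste0(fid, "_", sp)
        universe[[length(universe) + 1L]] <- data.frame(
          feature_id = inst, species = sp, chrom = "chr1",
          start = start, end = end, strand = "+",
          transcribed = TRUE, translated = FALSE, stringsAsFactors = FALSE)
        if (sp != focal) {
          add_map(fid, sp, start, end)
          add_hit(fid, inst, flen)
        }
      }
      genes[[length(genes) + 1L]] <- data.frame(
        feature_id = fid, species = focal, chrom = "chr1",
        start = start, end = end, strand = "+", biotype = "protein_coding",
        feature_class = "gene", stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <- data.frame(
        feature_id = fid, feature_class = "gene",
        planted_age = switch(kind, ortholog = "preserved",
                             species_specific_gene = "species_specific",
                             hominini_gene = "hominini_specific"),
        planted_structure = NA_character_, truncation = NA_real_,
        stop_codon_index = NA_integer_, stringsAsFactors = FALSE)
      next
    }

    # sORFs: plant the ORF in the focal genome
    orf_seq <- .random_orf(spec$sorf_codons)
    seqs[focal] <- .splice_seq(seqs[focal], start, orf_seq)
    orfs[[length(orfs) + 1L]] <- data.frame(
      orf_id = fid, host_gene = NA_character_, species = focal,
      chrom = "chr1", start = start, end = end, strand = "+",
      start_codon = "ATG", length_codons = spec$sorf_codons,
      n_samples_predicted = 3L + (i %% 4L), stringsAsFactors = FALSE)
    universe[[length(universe) + 1L]] <- data.frame(
      feature_id = fid, species = focal, chrom = "chr1",
      start = start, end = end, strand = "+",
      transcribed = TRUE, translated = TRUE, stringsAsFactors = FALSE)

    planted_age <- "species_specific"
    planted_structure <- NA_character_
    trunc <- NA_real_
    stop_idx <- NA_integer_

    if (kind == "sorf_denovo") {
      i_denovo <- i_denovo + 1L
      trunc <- trunc_vals[i_denovo]
      stop_idx <- as.integer(round((1 - trunc) * spec$sorf_codons))
      counter_seq <- .splice_seq(orf_seq, 3L * stop_idx, "TAA")
      planted_structure <- "de_novo"
    } else {
      counter_seq <- orf_seq
    }

    for (tsp in setdiff(species, focal)) {
      reads <- switch(kind,
                      sorf_preserved = 25L,
                      sample.int(5L, 1L) - 1L)  # 0..4, below the cutoff
      if (kind == "sorf_orphan") next           # region absent elsewhere
      seqs[tsp] <- .splice_seq(seqs[tsp], start, counter_seq)
      add_map(fid, tsp, start, end)
      translated_there <- kind == "sorf_preserved" ||
        (kind == "sorf_hominini" && tsp %in% hominini)
      if (translated_there) {
        inst <- paste0(fid, "_", tsp)
        universe[[length(universe) + 1L]] <- data.frame(
          feature_id = inst, species = tsp, chrom = "chr1",
          start = start, end = end, strand = "+",
          transcribed = TRUE, translated = TRUE, stringsAsFactors = FALSE)
        add_hit(fid, inst, flen)
        if (kind == "sorf_hominini") reads <- 30L
      }
      counterparts[[length(counterparts) + 1L]] <- data.frame(
        feature_id = fid, target_species = tsp, pooled_reads = reads,
        counterpart_seq = counter_seq, stringsAsFactors = FALSE)
    }

    planted_age <- switch(kind,
                          sorf_preserved = "preserved",
                          sorf_hominini = "hominini_specific",
                          "species_specific")
    if (kind %in% c("sorf_intact", "sorf_hominini")) {
      planted_structure <- "intact"
    }
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = fid, feature_class = "sORF", planted_age = planted_age,
      planted_structure = planted_structure, truncation = trunc,
      stop_codon_index = stop_idx, stringsAsFactors = FALSE)
  }

  # orphan sORFs in the focal-specific tail
  tail_pos <- L + spec$feature_spacing
  for (j in seq_len(spec$n_sorf_orphan)) {
    fid <- sprintf("sorf_orphan_%03d", j)
    orf_seq <- .random_orf(spec$sorf_codons)
    start <- tail_pos; end <- start + spec$sorf_span
    tail_pos <- end + spec$feature_spacing
    seqs[focal] <- .splice_seq(seqs[focal], start, orf_seq)
    orfs[[length(orfs) + 1L]] <- data.frame(
      orf_id = fid, host_gene = NA_character_, species = focal,
      chrom = "chr1", start = start, end = end, strand = "+",
      start_codon = "ATG", length_codons = spec$sorf_codons,
      n_samples_predicted = 3L + (j %% 4L), stringsAsFactors = FALSE)
    universe[[length(universe) + 1L]] <- data.frame(
      feature_id = fid, species = focal, chrom = "chr1",
      start = start, end = end, strand = "+",
      transcribed = TRUE, translated = TRUE, stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      feature_id = fid, feature_class = "sORF",
      planted_age = "species_specific", planted_structure = "orphan",
      truncation = NA_real_, stop_codon_index = NA_integer_,
      stringsAsFactors = FALSE)
  }

  list(sequences = seqs,
       genes = do.call(rbind, genes),
       orfs = do.call(rbind, orfs),
       target_features = do.call(rbind, universe),
       mapping = do.call(rbind, mapping),
       hits = do.call(rbind, hits),
       counterparts = do.call(rbind, counterparts),
       truth = do.call(rbind, truth),
       species = species,
       focal_species = focal,
       hominini = hominini)
}
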