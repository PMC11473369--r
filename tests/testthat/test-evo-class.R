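test_that("active_genes applies the mean and replicate thresholds", {
  m <- rbind(kept = c(0.6, 0.6, 0.6, 2.9),    # mean 1.175, 3 reps >= 0.5
             one_rep = c(4.0, 0, 0, 0),       # mean 1.0 but 1 rep >= 0.5
             low_mean = c(0.4, 0.4, 0.4, 0.4))
  colnames(m) <- paste0("s", 1:4)
  samples <- data.frame(sample_id = colnames(m), species = "human",
                        tissue = "LV", assay = "RNA", replicate = 1:4,
                        pairing_key = paste0("k", 1:4))
  act <- active_genes(m, samples)
  expect_equal(act$human, "kept")
  few <- samples[1:2, ]
  expect_error(active_genes(m[, 1:2], few), "unsatisfiable")
  act2 <- active_genes(m[, 1:2], few, min_reps = 1L)
  expect_true("one_rep" %in% act2$human)
})

test_that("replicated_orfs keeps >=3-sample ORFs on active hosts", {
  orfs <- data.frame(orf_id = c("o1", "o2", "o3"),
                     host_gene = c("gA", "gB", "gA"),
                     species = "human",
                     n_samples_predicted = c(3L, 5L, 2L))
  active <- list(human = "gA")
  kept <- replicated_orfs(orfs, active)
  expect_equal(kept$orf_id, "o1")  # o2 inactive host, o3 too few samples
})

test_that("collapse_orfs groups by in-frame overlap with AUG priority", {
  # AUG 60-codon ORF and GUG 63-codon ORF sharing 58 codons in frame
  orfs <- data.frame(
    orf_id = c("aug60", "gug63"),
    chrom = "chr1", strand = "+",
    start = c(9L, 0L), end = c(9L + 180L, 189L),
    start_codon = c("ATG", "GTG"),
    length_codons = c(60L, 63L), stringsAsFactors = FALSE)
  # shared positions 9..188 in frame (both frames start % 3 == 0)
  res <- collapse_orfs(orfs)
  expect_equal(length(unique(res$group)), 1L)
  expect_true(all(res$representative == "aug60"))  # AUG beats longer GUG

  # overlap at 80% of the shorter ORF: two groups
  far <- data.frame(orf_id = c("a", "b"), chrom = "chr1", strand = "+",
                    start = c(0L, 24L), end = c(120L, 144L),
                    start_codon = "ATG", length_codons = c(40L, 40L))
  res2 <- collapse_orfs(far)  # shared 96/120 = 0.8 < 0.9
  expect_equal(length(unique(res2$group)), 2L)

  # equal-length AUG ORFs: lexicographically smaller id wins
  tie <- data.frame(orf_id = c("zz", "aa"), chrom = "chr1", strand = "+",
                    start = 0L, end = 90L, start_codon = "ATG",
                    length_codons = 30L)
  res3 <- collapse_orfs(tie)
  expect_true(all(res3$representative == "aa"))

  # same span, shifted frame: never merged
  frames <- data.frame(orf_id = c("f0", "f1"), chrom = "chr1", strand = "+",
                       start = c(0L, 1L), end = c(90L, 91L),
                       start_codon = "ATG", length_codons = 30L)
  expect_equal(length(unique(collapse_orfs(frames)$group)), 2L)

  # opposite strands: never merged
  strands <- data.frame(orf_id = c("p", "m"), chrom = "chr1",
                        strand = c("+", "-"), start = 0L, end = 90L,
                        start_codon = "ATG", length_codons = 30L)
  expect_equal(length(unique(collapse_orfs(strands)$group)), 2L)
})

test_that("collapse_orfs is order invariant and matches the brute-force oracle", {
  set.seed(17)
  starts <- c(0L, 3L, 9L, 300L, 306L, 600L, 601L, 900L, 903L, 960L)
  lens <- c(150L, 150L, 141L, 90L, 90L, 120L, 120L, 210L, 210L, 150L)
  orfs <- data.frame(orf_id = sprintf("orf%02d", 1:10), chrom = "chr1",
                     strand = rep(c("+", "-"), 5),
                     start = starts, end = starts + lens,
                     start_codon = sample(c("ATG", "GTG"), 10, TRUE),
                     length_codons = lens / 3L, stringsAsFactors = FALSE)
  res <- collapse_orfs(orfs)
  oracle <- collapse_oracle(orfs)
  # same partition (groups equal up to renaming)
  expect_equal(length(unique(res$group)), length(unique(oracle)))
  expect_true(all(tapply(oracle, res$group, function(x) {
    length(unique(x)) == 1
  })))
  perm <- sample(nrow(orfs))
  res_perm <- collapse_orfs(orfs[perm, ])
  expect_equal(res_perm$representative[match(orfs$orf_id,
                                             res_perm$orf_id)],
               res$representative)
})

test_that("resolve_homologs follows the liftover/BLAST decision logic", {
  feats <- data.frame(feature_id = "q1", species = "human")
  targets <- data.frame(feature_id = "t1", species = "chimp", chrom = "chr1",
                        start = 100L, end = 200L, strand = "+",
                        transcribed = TRUE, translated = FALSE)
  empty_map <- data.frame(feature_id = character(),
                          source_species = character(),
                          target_species = character(),
                          target_chrom = character(),
                          target_start = integer(), target_end = integer(),
                          target_strand = character(),
                          colinear_flag = logical())
  hit <- data.frame(qseqid = "q1", sseqid = "t1", pident = 95, length = 100,
                    mismatch = 5, gapopen = 0, qstart = 1, qend = 100,
                    sstart = 1, send = 100, evalue = 1e-3, bitscore = 150)
  # E-value 1e-3 only, no liftover: fails the 1e-4 cutoff -> no homolog
  ev <- resolve_homologs(feats, c("human", "chimp"), empty_map, hit, targets)
  expect_false(ev$homolog_found)
  hit$evalue <- 1e-5
  ev2 <- resolve_homologs(feats, c("human", "chimp"), empty_map, hit, targets)
  expect_true(ev2$homolog_found)
  expect_equal(ev2$target_feature, "t1")

  # unique full mapping overlapping a transcribed target: homolog by liftover
  map <- data.frame(feature_id = "q1", source_species = "human",
                    target_species = "chimp", target_chrom = "chr1",
                    target_start = 120L, target_end = 180L,
                    target_strand = "+", colinear_flag = TRUE)
  ev3 <- resolve_homologs(feats, c("human", "chimp"), map, hit[0, ], targets)
  expect_equal(ev3$liftover_status, "unique_full")
  expect_true(ev3$homolog_found)
  expect_true(ev3$target_transcribed)

  # unknown species in the mapping table errors
  bad <- map; bad$target_species <- "yeti"
  expect_error(resolve_homologs(feats, c("human", "chimp"), bad, hit[0, ],
                                targets), "unknown species")
})

test_that("gene and ORF ages follow the homolog/translation rules", {
  ev <- function(tsp, found, transcribed, translated, reads) {
    data.frame(feature_id = "f", species = "human", target_species = tsp,
               liftover_status = ifelse(found, "unique_full", "none"),
               blast_best_evalue = NA_real_, target_feature = NA_character_,
               target_transcribed = transcribed,
               target_translated = translated,
               counterpart_reads = reads, homolog_found = found)
  }
  others <- c("chimp", "rhesus", "mouse", "rat")
  none <- do.call(rbind, lapply(others, ev, found = FALSE,
                                transcribed = NA, translated = NA, reads = 0))
  expect_equal(assign_gene_age(none)$age, "species_specific")

  chimp_only <- none
  chimp_only[1, c("homolog_found", "target_transcribed")] <- TRUE
  expect_equal(assign_gene_age(chimp_only)$age, "hominini_specific")

  rhesus_too <- chimp_only
  rhesus_too[2, c("homolog_found", "target_transcribed")] <- TRUE
  expect_equal(assign_gene_age(rhesus_too)$age, "preserved")

  # ORF: counterpart reads >= 10 anywhere force preserved
  reads12 <- none
  reads12$counterpart_reads <- c(12, 0, 0, 0)
  expect_equal(assign_orf_age(reads12)$age, "preserved")
  expect_equal(assign_orf_age(none)$age, "species_specific")

  # hominini ORF: translated homolog in chimp, tiny counterpart reads beyond
  hom_orf <- none
  hom_orf[1, c("homolog_found", "target_translated")] <- TRUE
  hom_orf$counterpart_reads <- c(30, 3, 0, 0)  # chimp reads don't count
  expect_equal(assign_orf_age(hom_orf)$age, "hominini_specific")
})

test_that("inframe_intact_fraction walks stops and frameshifts", {
  orf <- strrep("ATGGCCGAA", 34)           # 102 codons, stop-free
  orf <- paste0(substr(orf, 1, 300), "TAA")  # 100 codons + stop
  expect_equal(inframe_intact_fraction(orf, orf), 1.0)

  # stop planted at 0-based codon 20 -> fraction 0.20
  stopped <- paste0(substr(orf, 1, 60), "TAA", substr(orf, 64, nchar(orf)))
  expect_equal(inframe_intact_fraction(orf, stopped), 0.20)

  # 1-nt deletion inside codon 30 (0-based), no restoration -> 0.30
  aln_orf <- orf
  cp <- paste0(substr(orf, 1, 90), "-", substr(orf, 92, nchar(orf)))
  expect_equal(inframe_intact_fraction(aln_orf, cp), 0.30)

  # 3-nt (in-frame) deletion does not disrupt the walk
  aln3 <- paste0(substr(orf, 1, 90), "---", substr(orf, 94, nchar(orf)))
  expect_equal(inframe_intact_fraction(orf, aln3), 1.0)

  # counterpart ends early: intact up to its end
  short <- substr(orf, 1, 30)
  expect_equal(inframe_intact_fraction(orf, short), 0.10)
})

test_that("classify_structure applies the truncation rule and cutoffs", {
  fr <- data.frame(orf_id = c("a", "a", "b", "c"),
                   target_species = c("chimp", "rhesus", "chimp", "chimp"),
                   intact_fraction = c(0.2, 0.1, 0.95, NA))
  st <- classify_structure(c("a", "b", "c"), fr)
  expect_equal(setNames(st$structure, st$orf_id),
               c(a = "de_novo", b = "intact", c = "orphan"))

  # 'all' vs 'any' rule
  mixed <- data.frame(orf_id = "m", target_species = c("chimp", "rhesus"),
                      intact_fraction = c(0.2, 0.9))
  expect_equal(classify_structure("m", mixed, rule = "all")$structure,
               "intact")
  expect_equal(classify_structure("m", mixed, rule = "any")$structure,
               "de_novo")

  # raising the cutoff monotonically shrinks the de novo set
  set.seed(30)
  many <- data.frame(orf_id = sprintf("o%03d", 1:100),
                     target_species = "chimp",
                     intact_fraction = runif(100))
  cuts <- c(0.5, 0.7, 0.9)
  sizes <- vapply(cuts, function(ct) {
    sum(classify_structure(many$orf_id, many,
                           truncation_cutoff = ct)$structure == "de_novo")
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})
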