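---
title: "Methods: cross-species translatome analysis with ribevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-species translatome analysis with ribevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribevol)
```

# Scope and model

`ribevol` analyzes the evolution of translational control in designs that
pair Ribo-seq (in-frame P-site counts) with RNA-seq across several
species and many biological replicates per species. Its quantities of
interest are:

* **Translational efficiency (TE)** — per gene and sample pair, the ratio
  of normalized ribosome-footprint density to normalized mRNA abundance.
* **TE_var** — a per-gene score of *between-species* TE variance corrected
  for *within-species* sampling noise.
* **Regulatory modes** — for genes whose TE shifts in one focal species:
  buffering (TE opposes an mRNA change), exclusive (TE changes with no
  mRNA change), intensified (TE amplifies an mRNA change).
* **Evolutionary ages and structures** — species-specific /
  hominini-specific / preserved calls for genes and small ORFs from
  liftover-style mapping and BLAST evidence, and intact / de novo /
  orphan structural classes for young sORFs.
* **Tissue specificity (tau) and co-regulation** — the tau index on a
  tissue atlas of mean expression, and Spearman partner sets around focus
  genes.

## TE and its normalization order

Raw counts are first divided by CDS length in kb (`length_adjust()`),
then size-factor normalized across **all samples and species of one
assay jointly** (`size_factors()`, median-of-ratios over genes with no
zero count; with an even reference count the median is the mean of the
two central ratios). RNA and Ribo libraries are normalized separately
because TE is a ratio of two independently normalized assays. Length
adjustment precedes cross-sample normalization; this order matters
because the reference-gene geometric means are computed on
length-adjusted values.

A consequence of the shared per-gene geometric-mean reference is worth
stating: multiplying one sample's counts by `c` multiplies that sample's
factor by `c` **relative to the unscaled samples** (the absolute factors
all absorb `c^(1/n)` through the reference). The tests assert the exact
relative form.

TE is computed per matched sample pair. The default scale is log2 with a
pseudocount of 1 added to both normalized counts before the ratio;
`scale = "linear"` and `pseudocount = 0` give the plain ratio. Log2 is
the default because linear TE ratios are heavy-tailed and variance
decompositions on them are dominated by a few low-expression genes; the
pseudocount bounds the influence of near-zero denominators. Genes are
excluded from all TE calculations when, within any species and either
assay, the raw replicate counts have a median of 0 or at least 3 zeros.

## TE_var

For each gene, with per-species TE values:

1. per species *s*: sampling variance = Var(TE over individuals of *s*)
   / *n_s* (sample variance, n−1 denominator);
2. `avg_sampling_variance` = mean of those over species;
3. `across_species_variance` = Var over species of the per-species mean
   TE (again n−1);
4. `te_var = across_species_variance − avg_sampling_variance`.

The subtraction makes the estimator unbiased for the planted
between-species variance under the generative model below, regardless of
count noise: the across-species variance of species means has expectation
`sigma_between^2 + (total within variance)/n`, and the subtracted term
estimates exactly the second part. Negative values are reported rather
than clamped — clamping would bias group medians upward. Species
contributing a single retained sample are excluded from both terms.

Two naming conventions circulate for the two variance levels; `ribevol`
avoids the ambiguity by calling them `across_species_variance` (variance
of species means) and `avg_sampling_variance` (averaged within-species
variance of the mean).

## Resampling and downsampling inference

Group-level significance uses a permutation design that relabels **whole
samples** to species (without replacement, preserving each species'
sample count), not per-gene values, so all gene–gene correlation is
preserved under the null. Each of the (default 10,000) iterations
recomputes `te_var` for every gene and the median over each tested gene
group. The one-sided p-value is the fraction of permuted medians strictly
greater than the observed one — ties count as non-exceeding, and the
resolution floor is 1/iterations, so a reported 0 means "below
1/iterations". P-values are Benjamini–Hochberg adjusted across the tested
groups ("FDR correction" is otherwise unspecified; BH is the field
default).

Robustness to unequal replication is assessed by downsampling: each
iteration draws k samples per species without replacement and recomputes
the group median; the 2.5th/97.5th percentiles of the iteration medians
are reported. When k equals every species' sample count the interval
degenerates to the observed median, which the tests assert.

## Differential tests and regulatory modes

The original analysis engine for differential expression is a
negative-binomial GLM, which is deliberately out of scope here. The
package ships two documented stand-ins that produce the same table
schema (`feature_id`, `log2_fold_change`, `adjusted_p`, `significant`),
so externally produced tables can be swapped in anywhere:

* `standin_de_test()` — per-gene Welch t-test on log2(normalized + 1);
* `te_species_test()` — focal species vs pooled others on log2 TE, with
  a label-permutation p-value (add-one corrected, two-sided).

Significance always requires both an absolute fold change of at least
1.5 and an adjusted p below 0.05. Mode classification uses only
significant fold-change signs: for TE-significant genes, RNA-significant
with opposite sign is buffering, same sign intensified, RNA
non-significant exclusive. The three modes partition the TE-significant
set exactly; the sign of a non-significant fold change is never
consulted.

## Evolutionary classification

Activity filters: a gene is actively transcribed in a species when its
mean FPKM is ≥ 1 and at least 3 replicates reach FPKM ≥ 0.5; an ORF is
replicated when predicted in ≥ 3 samples on an active host gene. ORF
isoforms collapse when they share ≥ 90% of the shorter ORF's in-frame
genomic positions (same strand and frame; grouping is transitive);
representatives prefer AUG starts, then length, then the
lexicographically smallest id. The 90% rule is applied on nucleotide
positions with the shorter ORF as denominator, so containment collapses.

Homology per (feature, target species) combines two channels: a
liftover-style mapping is accepted when the feature maps fully to a
unique counterpart region on one strand and chromosome, and the homolog
is the target-universe feature with the longest overlap to that region;
a BLAST hit is accepted at E ≤ 1e-4. The search universe is all
transcribed genes / all predicted ORFs of the target species (not only
the filtered active sets), to maximize homolog detection.

Ages: no homolog anywhere → species-specific; homolog activity confined
to the hominini partner → hominini-specific; otherwise preserved. For
ORFs, a young call additionally requires fewer than 10 pooled Ribo-seq
reads in every counterpart region that lacks a detected translated
homolog — read evidence of unclear identity disqualifies youth, while a
species with a detected translated homolog is judged by that homolog.

Structures (young sORFs only): no aligned counterpart → orphan; all
aligned counterparts truncated by ≥ 70% of the in-frame sequence →
de novo; otherwise intact. The intact fraction is measured by walking
the counterpart in the ORF's frame from the aligned start; the walk ends
at the first in-frame stop codon, at an accumulated gap length that is
not a multiple of 3 (no frame-restoration scanning — the simplest
monotone rule, since no restoration convention is established), or at
the counterpart's end. Whether the truncation rule must hold in **all**
aligned species or **any** is genuinely open; the default is the
conservative `all` (tracing birth on the ancestral lineage), with
`rule = "any"` available.

## Tau and co-regulation

Tau uses the standard formula `sum(1 - x_i/max) / (n - 1)` on mean
expression per tissue, after excluding testis by default (pervasive
testis transcription inflates apparent specificity of young genes). A
gene is tissue enriched at tau > 0.75 **and** an unambiguous argmax
tissue — tau alone does not name a tissue, and argmax ties yield no
assignment (conservative). "Recently enriched" genes are enriched with
the focal tissue maximal in the focal species and not so in any other
species. Co-regulation edges are Spearman correlations on
pairwise-complete normalized expression, restricted to genes detected
(≥ 1 raw count) in a minimum number of samples, with edges kept at
|rho| > 0.5.

# The synthetic world

`simulate_counts()` draws, for gene g, species s, replicate r:

```
log2 TE_gsr = mu_g + B_gs + W_gsr,  B ~ N(0, sigma_between^2),
                                    W ~ N(0, sigma_within^2)
RNA_gsr  ~ NB(mean = lib_r * len_kb_g * 2^E_gs,            dispersion)
Ribo_gsr ~ NB(mean = lib_r * len_kb_g * 2^(E_gs + log2TE), dispersion)
```

with the mean/dispersion NB parameterization
(`Var = mu + mu^2/dispersion`), stated explicitly to avoid shape
ambiguity. Defaults emulate a five-species left-ventricle design
(15/5/4/6/5 replicates), ~128 mean counts per kb (gene baseline log2
expression ~ N(7, 1)), dispersion 10 (moderate biological
overdispersion), sigma_between = sigma_within = 0.5 on log2 TE, CDS
lengths uniform on 300–3000 nt, and per-sample, per-assay library scale
factors log-uniform on (0.7, 1.4) — drawn and recorded in the truth so
normalization is genuinely exercised. Regulation-mode genes shift RNA
and TE by configured log2 fold changes in the focal (first) species
only. One global seed drives everything; identical configs reproduce
byte-identical matrices.

What the generator does **not** emulate: splice isoforms, sequencing
error, mappability artifacts, correlated gene–gene expression programs,
tissue mixtures, and phylogenetic covariance between species (species
effects are exchangeable). A green recovery test therefore establishes
correctness of the estimators under the stated model, not robustness to
every feature of real data.

`simulate_toy_genomes()` plants, in single-chromosome genomes: colinear
orthologs (reciprocal hits at E = 1e-30), focal-only and hominini-only
genes (no mapping/hit rows where absent), and sORFs whose counterparts
are identical (intact), carry an engineered premature stop at codon
`round((1 - truncation) * L)` (de novo; exact to the codon by
construction), or lie in a focal-only chromosome tail (orphan — the
region is genuinely absent elsewhere). Preserved sORFs get translated
counterpart features and pooled counterpart reads above the 10-read
cutoff; young ones stay below it. Features are auto-placed with spacing,
so overlapping placements are impossible by construction and an
oversubscribed chromosome is rejected at spec time.

`simulate_tissue_atlas()` plants specific genes at a 10-fold excess in a
designated tissue over a log-normal baseline with multiplicative noise
(log-SD 0.1 by default; 0 gives exactly uniform backgrounds with tau 0).

# Numerical choices and degenerate inputs

* Sample variance uses n−1 denominators at both levels of TE_var.
* Permutation p for group medians uses strict `>` (ties non-exceeding);
  the species-contrast stand-in uses the add-one estimator
  `(1 + exceed)/(1 + iterations)` because its p-values feed a BH step
  where exact zeros would be anticonservative.
* Zero-variance genes in the Welch stand-in get p = 1 and are logged.
* All-zero genes are skipped by tau with a warning; argmax ties get no
  tissue.
* Constant vectors yield no co-regulation edge (rho undefined).
* Internal coordinates are 0-based half-open everywhere; GTF (1-based
  closed) is converted at the IO boundary only, and minus-strand
  sequence extraction reverse-complements at read time.
* `te_var` decomposition identity is exact by construction and asserted
  for every output row.

# Known limitations

* The DE stand-ins are validated against planted truth only; they are
  not expected to reproduce NB-GLM gene lists on real data. Import
  externally computed tables for that.
* TE_var's permutation null assumes exchangeable samples across species;
  designs with strong batch structure need a restricted permutation
  scheme not implemented here.
* The intact-fraction walk does not scan for frame restoration after a
  frameshifting gap; counterparts with compensated double gaps are
  scored as truncated at the first event.
* `resolve_homologs()` evaluates features one at a time against
  data-frame evidence tables; it targets desk-scale evidence (tested to
  a few hundred features × species), not genome-wide scans.
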