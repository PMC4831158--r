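---
title: "Methods: GBS population genomics in acropipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GBS population genomics in acropipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, parameter choices and
numerical decisions behind the package, in the order a dataset moves
through the pipeline.

## The data model

A panel is a `genotype_matrix`: samples × biallelic loci, each call the
alt-allele dosage 0/1/2 or missing, optionally with the read depth
supporting every call. A companion `population_map` assigns each sample
to a population, each population to a group (e.g. a region), and records
collection coordinates in decimal degrees. All positions are 1-based,
matching VCF and HapMap conventions; dosage counts the alt allele as
written in the file — no strand flipping is attempted.

## Read retention

GBS libraries put the sample barcode and the restriction cut-site
remnant at the 5′ end of every read. `demultiplex_trim()` keeps a read
iff it starts with a registered barcode immediately followed by a
remnant motif (`CAGC`/`CTGC` for ApeKI), then trims to a 64-bp tag
starting *at the remnant*, discarding the barcode. Two deliberate
choices keep the stage deterministic and auditable: barcode matching is
exact (no mismatch rescue — any tolerance rule would need an error model
we do not have), and reads with a valid prefix but fewer than 64 bases
after the barcode are discarded and counted separately. Only the 5′ end
is checked, as appropriate for single-end protocols.

## The QC cascade

`run_cascade()` applies six stages in a fixed, documented order:
consensus → depth mask → call-rate fixpoint → MAF → heterozygote excess
→ LD pruning. The order is a package decision (upstream tools interleave
some of these internally); each stage is idempotent and every stage is
logged with in/out counts and removed identifiers, so the full cascade
is reproducible and auditable.

* **Dual-caller consensus** (`af_delta = 0.05`). Aligner choice shifts
  allele frequencies at mis-mapped loci, so only loci reported by both
  callers with |AF₁ − AF₂| ≤ 0.05 survive; calls are taken from the
  first caller. The tolerance is a package default: "similar allele
  frequencies" needs a number, and 0.05 matches the MAF resolution of
  panels this size.
* **Depth mask** (`min_depth = 5`). "Five reads per locus" is read as
  per-genotype support: a call backed by fewer than 5 reads becomes
  missing but keeps its depth (a masked call is not a deleted one).
* **Call-rate fixpoint** (70 % per individual, 90 % per locus). The two
  thresholds interact — dropping a bad sample raises locus call rates
  and vice versa — so the filter iterates to a joint fixpoint. Among
  all currently failing samples and loci, the single worst offender
  (lowest call rate, samples winning ties) is removed and all rates
  recomputed. This greedy rule is deterministic, logged step by step,
  and on small matrices it reaches the cell-count-optimal fixpoint
  found by exhaustive search (tested).
* **MAF** (≥ 0.05, inclusive — "at least 5 %"), computed over
  non-missing calls; all-missing loci are removed and counted apart.
* **Heterozygote excess** (exact one-sided test, `p < 0.01`). In GBS
  data a locus where two paralogous regions co-align looks like a SNP
  with far too many heterozygotes. The exact conditional test on the
  heterozygote count given allele counts (the standard factorial
  formula, evaluated in log space) is used one-sided: deficits are
  never removed, because inbreeding and substructure legitimately
  produce them while the technical artefact inflates only the excess
  side.
* **LD pruning** (D′ chi-square p < 0.01 **or** r² > 0.20, 100-SNP
  window, later locus removed). Haplotype frequencies are estimated
  from unphased genotypes by EM under HWE (only double heterozygotes
  are ambiguous; 100 iterations, convergence 10⁻¹⁰), D significance by
  the 2n·D²/(p_A q_A p_B q_B) chi-square; r² is the composite
  genotypic correlation, robust without phase. Pairs are only tested
  *within a scaffold*: loci on different scaffolds carry no linkage
  information, and testing the ~99 cross-scaffold "pairs" per window at
  α = 0.01 would prune a majority of a panel by false positives alone.
  Pairs with fewer than 5 complete genotype pairs, or monomorphic in
  the complete subset, are never flagged. Removing the *later* locus in
  genome order is an arbitrary but deterministic tie-break.

## Diversity

`pairwise_pi()` computes, for every sample pair, the proportion of
mutually called loci at which the genotype calls differ. Any difference
(0 vs 1, 1 vs 2, 0 vs 2) counts once — this is a genotype-mismatch
distance, not an allele-sharing distance; the latter (|dosage
difference|/2) is available as an option. Denominators are
pairwise-complete, the standard pairwise-deletion treatment of
missingness. Because SNP panels ignore invariant sites, π on this scale
overstates per-nucleotide diversity; `adjusted_pi()` rescales by the
observed SNP density per sequence tag (π · SNPs-per-tag / 64). Expected
heterozygosity uses the plug-in 2p(1−p); the 2n/(2n−1) small-sample
factor is an optional flag.

## Population structure

**FST.** The Weir–Cockerham (1984) estimator is implemented from the
variance components a (among populations), b (among individuals within
populations) and c (within individuals); θ = a/(a+b+c). Multi-locus
values combine loci as Σa/Σ(a+b+c) — the ratio of sums, which is far
less noisy than averaging per-locus ratios. Loci where fewer than two
populations have ≥ 2 genotyped individuals, or that are monomorphic
overall, are flagged undefined and skipped in sums. Negative multi-locus
estimates are reported raw and shown truncated at zero in the output
table, the conventional presentation. Significance comes from permuting
*individuals* between populations — permuting alleles would destroy the
within-individual (Hardy–Weinberg) structure that the estimator's b and
c components measure — with p = (1 + #{θ\* ≥ θ})/(n_perm + 1), so p is
never exactly zero.

**AMOVA.** Each genotype contributes two allelic observations; the
squared distance between allele copies is 0/1. Sums of squares are
computed per locus from the identity SS = Σ_{i<j} d²_{ij}/n and summed
over loci, partitioned into among-group / among-populations-within-group
/ within-population strata (the partition is exactly additive, tested to
machine precision against a brute-force distance-matrix evaluation).
Variance components use the standard nested-ANOVA coefficients for
unequal sizes. Degrees of freedom and coefficients are computed from
individual counts (2N copies) even when some calls are missing — with
sparse missingness the distortion is negligible and the permutation
tests remain exact by construction. Permutation strata: individuals
among all populations (Φ_ST), individuals among populations within
their group (Φ_SC), whole populations among groups (Φ_CT). With few
populations the Φ_CT permutation space is small and its p-value coarse;
this is inherent to the design, not a defect. Degenerate designs (one
population per group, or a single group) drop the empty stratum and
report its component as zero with an NA p-value.

**Outlier scan.** `fdist_outliers()` tests each locus's θ against a
neutral distribution simulated under a Balding–Nichols island model:
ancestral frequency uniform on (0.02, 0.98), population frequencies
Beta(p(1−F)/F, (1−p)(1−F)/F), genotype counts multinomial under HWE with
sample sizes matched to the data (median genotyped individuals per
population). A coalescent engine would model deme number and migration
explicitly; the Balding–Nichols surrogate gives exact control of F at
desk scale and preserves the conditional-on-heterozygosity logic that
makes FDIST work. Simulated loci are binned by total expected
heterozygosity (width 0.04 — narrow enough to track the He–θ dependence,
wide enough to keep hundreds of simulated loci per bin; sparse bins are
widened symmetrically with a warning). Per locus,
p = (1 + #{θ_sim ≥ θ})/(n_bin + 1); `significant` means p below 0.01 and
`outlier` means θ above the bin's 99 % quantile — both flags are
reported because "significant" and "outlier" answer slightly different
questions. When no background F is supplied it is calibrated from the
data: ratio-of-sums θ over all loci, a provisional simulation (one fifth
of `n_sim`), removal of loci outside the provisional 1 %/99 % envelope,
and one recomputation of the ratio-of-sums on the remainder. No multiple
testing correction is applied by default (raw p < 0.01 is the reported
convention); Benjamini–Hochberg can be applied downstream with
`p.adjust`.

## Isolation by distance

Geographic distances are haversine great-circle distances with Earth
radius 6371.0 km (collection coordinates are lat/lon, so a projected
Euclidean distance would need a zone choice; over hundreds of km the
difference is well under the coordinate uncertainty). Genetic distances
are Euclidean on dosage vectors over pairwise-complete loci, divided by
√(loci used) so pairs with different missingness are comparable; the
default locus subset is the set flagged by the per-locus FST permutation
test, restricting the signal to loci that actually differentiate
populations. The Mantel statistic is the Pearson correlation of
lower-triangle entries; one matrix's rows and columns are permuted
jointly, and the default p-value is two-sided (|r\*| ≥ |r|) since the
direction of a distance correlation is not specified in advance.

## The synthetic-data generator

`simulate_island_genotypes()` produces panels with the statistical
structure the analyses assume, plus full ground truth. Defaults encode
the study design the package targets: five populations (23, 10, 10, 23
individuals in one group; 11 in a second group, mirroring a
four-populations-plus-outgroup sampling plan), 4,764 loci, ancestral
MAF uniform on [0.05, 0.5] (resembling a post-MAF-filter panel),
background F = 0.05 (the middle of the 0.01–0.09 range typical of
weakly structured marine populations), 2 % outlier loci at F = 0.4,
five 3-locus LD blocks, 3 % missingness, negative-binomial depths with
mean 411 and size 2, 500 scaffolds, populations spaced 60 km along a
latitudinal transect with ±2 km jitter. Stepping-stone mode chains the
Beta draws along the transect so differentiation grows with distance —
the configuration used to validate the Mantel test. LD blocks are
placed within single scaffolds (the pruner never tests across
scaffolds) and are built by per-individual copying from the block's
first locus, giving dosage correlation ≈ the copy probability.

What the generator does *not* emulate: clonality (every simulated
individual is an independent genet), linkage beyond the planted blocks,
allele-frequency spectra shaped by selection or demography, sequencing
error in the genotype calls themselves, and the alignment process that
produces real dual-caller discordance (`simulate_caller_pair()` mimics
its *effect* — partial locus overlap and shifted allele frequencies —
not its mechanism). Passing tests therefore demonstrate estimator
correctness under the stated model, not robustness to every property of
real GBS data.

`simulate_gbs_reads()` writes FASTQ with a configurable fraction of
valid reads (barcode + remnant), corrupting the rest in either the
barcode or the remnant, with per-read truth labels.

## Reproducibility and problem sizes

Every stochastic function takes an explicit seed and restores the
caller's RNG state; the pipeline derives one child seed per stage from
its master seed, so reruns reproduce every result table. The validation
suite runs at deliberately reduced sizes chosen to keep Monte-Carlo
error well inside the tested tolerances: FST recovery on 4 × 20
individuals at 5,000 loci (±0.01 around F = 0.05), permutation
calibration on 200 null splits with 299 permutations each, outlier
calibration and power at 2,000 observed and 20,000 simulated loci
(scaled from the 100,000 a full analysis would use), and exact oracle
equivalences on fixtures small enough for exhaustive enumeration.

## Known limitations

* π is a genotype-mismatch proportion; published values computed with
  phylogenetic distance routines may treat heterozygotes differently,
  so cross-study comparisons of absolute π should use the documented
  definition rather than assuming bit-level agreement.
* The exact HWE filter pools all samples; with strong substructure a
  Wahlund-corrected (stratified) test would be less aggressive. The
  pooled test is the conservative choice for artefact removal.
* AMOVA treats loci as independent after LD pruning; residual linkage
  inflates the apparent number of independent observations, a caveat
  shared with all SNP-count AMOVAs.
* The outlier scan's neutral model is an island model; under strong
  hierarchical structure its type-I error can exceed nominal levels at
  loci with extreme heterozygosity, a known property of FDIST-style
  tests.
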