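---
title: "Testing localized introgression at color-pattern loci: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing localized introgression at color-pattern loci: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Müllerian co-mimics — distantly related, unpalatable butterfly species that
converge on the same warning color pattern — pose a sharp population-genomic
question: did the shared pattern arise independently in each species, or was
a color-pattern allele exchanged between them by introgression? Genome-wide
admixture statistics can miss an introgressed region of a few hundred kb, so
the test has to be *local*: infer genealogies in small windows around the
color locus, ask how often the co-mimetic subspecies of the two species
cluster together, and calibrate that count against a null that preserves the
local autocorrelation of genealogical signal.

`introtopo` implements that test end to end, together with the surrounding
statistics a study of this kind runs: genome-wide f4 tests of allele
sharing, windowed fd/fdM scans, pooled nucleotide diversity, a trans-species
polymorphism classifier, and the post-processing of a genome-wide
association (GWA) scan for a discrete wing phenotype. A coalescent
simulator with an introgressed tract generates data with the assumed
structure, so every stage is testable without any external download.

# The localized-introgression test

## Quartet design

The unit of analysis is a quartet of taxa: two species (A, B), each
represented by two morphologically distinct subspecies — sspA1 and sspB1
share a wing phenotype (the co-mimics), sspA2 and sspB2 do not. Roles are
fixed in configuration *before* any data are seen:

* species topology `(A1,A2)|(B1,B2)` — expected under the species tree;
* introgression topology `(A1,B1)|(A2,B2)` — co-mimics clustering;
* the third arrangement `(A1,B2)|(A2,B1)`.

Declaring the "introgression-compatible" topology in advance (rather than
picking the most common non-species topology post hoc) prevents circularity:
incomplete lineage sorting (ILS) produces both alternative topologies at
equal rates, and only an excess of the *declared* one is evidence.

## Windowed genealogies

Windows are nonoverlapping blocks of exactly 100 SNPs in SNP-index space
(`make_windows`); the trailing remainder is dropped. Per window we compute
haplotype p-distances (proportion of mismatching co-called sites; any
mismatch counts 1, so multiallelic codes are tolerated) and build an
unrooted neighbor-joining tree with `ape::nj`, clamping negative branch
lengths to zero. Windows in which some haplotype pair has no co-called
sites are dropped and logged — a tree is undefined there, and imputation
would manufacture signal.

## Topology weights

For a window tree, the weight of topology τ is the fraction of tuples (one
haplotype from each of the four groups) whose induced quartet in the tree
equals τ (`weight_window`). Enumeration is exhaustive up to 50,000 tuples
and Monte Carlo (10,000 with-replacement draws) beyond; weights always sum
to 1. Induced quartets are read off the topological (unit-branch-length)
leaf distance matrix: in a binary tree the three quartet pair-sums differ by
at least two edges, so the argmin is exact even when estimated branch
lengths are zero. NJ always returns a binary resolution and that stored
resolution counts; weights are not split across unresolved alternatives.

A window is *intro95* when the introgression-topology weight is at least
0.95 (boundary inclusive). The test statistic is the intro95 count among
windows whose bp midpoint falls in a focal region (the GWA peak / color
locus), `intro95_count`.

## Block-permutation null

Significance comes from shuffling the genome in 100-kb blocks
(`permute_and_test`): blocks tile the track span (the trailing partial
block participates; dropping it would bias the span), windows travel with
their block and are re-addressed to the bp interval their block occupies
after the shuffle, and the intro95 count is recomputed over the *fixed*
focal coordinates. This destroys any association between genealogical
signal and position while preserving within-block autocorrelation. The
p-value uses the add-one convention `p = (1 + #{null >= obs}) / (1 + n_perm)`
(50,000 permutations by default), so it is never exactly zero; when no
window anywhere is intro95 the result is reported as p = 1 with a
`degenerate` flag rather than "incomputable".

Two design notes a user should know:

* The test is *discrete*. With few blocks, or few intro95 windows, the null
  count distribution has heavy ties and the test is conservative (rejection
  below nominal α). It approaches nominal calibration as the region grows;
  analyses of this kind are typically run on multi-Mb regions around the
  peak, and the calibration simulations below use a 2-Mb region for that
  reason. The focal region should span several blocks — if it covers a
  single block, the smallest attainable p is roughly 1/(number of blocks).
* Whether the original block-permutation preserved window adjacency across
  block joins exactly as here cannot be pinned down from published
  descriptions; the calibration results below are what make the implemented
  null defensible on its own terms.

# The coalescent simulator

`simulate_haplotypes` draws, for each non-recombining segment (5 kb by
default), one genealogy from the structured Kingman coalescent on the
population tree `((A1,A2),(B1,B2))`, then drops infinite-sites mutations as
Poisson(θ/2 × branch length × segment bp) with uniform positions. Times are
in units of 2N generations; `theta_within` is the per-bp scaled mutation
rate (4Nμ), so expected within-population pairwise diversity per bp equals
`theta_within` exactly (a within-population pair always coalesces at rate 1
on this tree). There is no recombination within segments, no selection, no
size change — the generator reproduces the *statistical structure* the
analyses assume (window-scale genealogical heterogeneity, species-tree
concordant background, an optional introgressed tract), not the full
complexity of real genomes. Passing tests therefore validate the machinery,
not robustness to gene conversion, repeat content, or phasing error.

Introgression is modeled as a backward-time lineage reassignment, not a
haplotype copy-paste: each A1 haplotype independently carries the tract
with probability `introgression_fraction` (drawn once per simulation, so
the same haplotypes carry every tract segment and the causal allele is
coherent); within tract-overlapping segments, carrier lineages form their
own deme — they may coalesce with each other, sharing the introgressed
background — and merge into B1 at `introgression_time`. A causal SNP is
planted at `causal_pos`: all B1 haplotypes and all carriers hold the
derived allele, and each diploid's phenotype follows the configured
dominance (recessive by default: phenotype 1 iff homozygous derived —
matching systems where the shared-pattern allele is recessive).

One dynamical point mattered enough to record: the introgression signature
(A1 clustering with B1) requires carrier lineages to coalesce *inside the
B1 deme before B2 merges in*. If the subspecies split is shallow relative
to the coalescent timescale, carriers survive into the joint B pool and
pair with B1 and B2 at equal rates — the signal moves into the third
topology, not the introgression topology. Simulation designs with an
introgressed tract therefore use deep subspecies splits (defaults: split
times 1.0 and 2.0), which is also the biologically relevant regime:
co-mimics are distantly related species, and an adaptively introgressed
color allele is typically fixed in the recipient subspecies
(`introgression_fraction = 1` in the demonstration and power analyses).

The 4-population frequency simulator (`simulate_frequencies`) is a
Balding–Nichols model: ancestral frequencies uniform on (0.05, 0.95), each
population a Beta draw with drift parameter F (default 0.1), plus an
optional admixture edge replacing the recipient's frequency with a mixture.

# Study designs used by the tests and the acceptance script

All sizes were chosen once, as the smallest designs that exercise each
property clearly; they are stated here as the package's own choices.

* **Null calibration** (200 replicates, n_perm = 1000): a 2-Mb chromosome,
  one diploid per subspecies, θ = 0.012, split times 1.0 / 1.3, focal =
  8 of 20 blocks. The short internode maximizes ILS at the species boundary
  (each alternative quartet topology has probability e^(−0.3)/3 ≈ 25%), so
  intro95 windows occur under the null — about 7% of windows — and the
  permutation statistic has enough mass to be informative. Rejection at
  α = 0.05 must fall inside the exact binomial 95% interval around 0.05.
* **Power** (50 replicates): 1-Mb chromosome, θ = 0.006, default deep
  splits, a fully introgressed 400-kb tract equal to the focal region,
  pulse at time 0.01. Rejection rate must be at least 0.8; in practice it
  is essentially 1.
* **GWA recovery** (100 replicates): 15 diploids per subspecies over
  100 kb with a fully introgressed 40-kb tract and causal SNP at its
  center. Phenotypes are noiseless given the causal genotype (discrete
  wing forms; intermediates are out of scope). With fixed carriers there
  are no heterozygotes at the causal site, so ρ² = 1 there and the
  fully-associated interval must contain the causal position in ≥95% of
  replicates.
* **f4 calibration** (100 replicates each): 20,000 sites at 1-kb spacing
  (40 jackknife blocks). Null: |Z| < 3 in ≥95% of replicates. Admixture
  (donor pop3 → recipient pop1, m = 0.2, sympatric pair in the A/C slots):
  mean f4 positive.

# The surrounding statistics

**f4 with weighted block jackknife** (`f4_stat`): mean over usable sites of
(pA−pB)(pC−pD); sites with any undefined frequency are skipped, never
imputed. The standard error is a delete-one-block weighted jackknife over
nonoverlapping 500-kb physical blocks (weights ∝ usable sites per block;
empty blocks dropped; fewer than two blocks leaves the SE undefined and
flagged). The arrangement convention puts the sympatric same-location pair
in the A and C slots so that excess sympatric sharing gives positive f4.

**fd / fdM** (`fd_window`): computed on derived-allele frequencies
(polarize upstream with `assign_ancestral`, which uses the outgroup major
allele and falls back to the majority allele across all samples, ties to
the reference). Windows default to 20 kb with at least 20 informative
sites — no published window size exists for this step, so these are
declared defaults, not inferred ones. fd is reported only where the window
ABBA–BABA numerator is positive (the raw numerator is always retained);
fdM is the signed variant, normalized for a P3→P2 donor when the numerator
is non-negative and for a P3→P1 donor (sign retained) otherwise.

**Pooled diversity** (`pooled_pi`): the invariant-site-aware ratio-of-sums
estimator — discordant allele pairs over comparable pairs, summed across
sites before dividing, in 50-kb windows. Inputs should include invariant
sites; repeat masking is an input concern (mask before, or pass a masked
VCF), not done here.

**Trans-species polymorphism** (`classify_transpoly`): a biallelic site is
trans-polymorphic when (i) ≥4 species are polymorphic if more than three
species have data, or (ii) all species with data are polymorphic if three
or fewer; and (iii) each allele has ≥6 copies counted across *all* species.
"Polymorphic within a species" means both alleles occur among that
species' called alleles — the weakest literal reading, as no per-species
count floor is published. Copies are counted across all species, not just
polymorphic ones; the alternative reading exists and would be stricter.
Multiallelic sites are out of scope for this classifier.

**GWA post-processing** (`association_scan`, `assoc_table`): the upstream
mixed-model scan is deliberately replaced by a plain trend test (n·r²
against χ²₁ on called samples) — this package's concern is the
*post-processing*, and population-structure correction is a non-goal. The
scan is calibrated (uniform p under permuted phenotypes) at the sample
sizes used here. Downstream: Bonferroni threshold α/n_tests; ρ² = squared
midrank Spearman correlation between dosage and phenotype code ({0, 0.5, 1},
treated as ordinal); "fully associated" operationalized as ρ² = 1 on called
samples; the fully-associated interval reported with 1-based inclusive
endpoints (length = end − start + 1), matching how genomic peak coordinates
are printed. −log10(p) is capped at 320 for export.

**Diagnostic motif scan** (`diagnostic_motif_scan`): enumerate k-mers
(k = 6–12) overlapping fixed SNPs in either homozygote group's sequences;
a hit is diagnostic when present (substring containment per sequence) in
100% of one group and 0% (strict) or <5% (relaxed) of the other. The
occurrence filter is exposed as configurable min/max bounds because the
published exclusion rule ("occurred less than 3 times per sequence") reads
ambiguously.

# Numerical conventions

* Internal coordinates are 0-based half-open; VCF I/O is 1-based.
* MAF filter boundary inclusive (≥ 0.10), missingness strictly below 0.25;
  missing genotypes are excluded from the MAF denominator.
* NJ ties and negative branches: `ape::nj` resolution, negatives clamped
  to 0, topology kept.
* Ancestral-allele ties resolve to the reference allele.
* Monte Carlo weight draws and all permutations consume the caller-seeded
  RNG; the two simulators call `set.seed` internally (frequency simulation
  offsets the seed by 1000 so the two generators never share a stream).
* Degenerate inputs fail loudly (empty quartet groups, <4 taxa, zero
  permutations) or return flagged missing values (undefined SE, no fully
  associated SNPs, windows with no data) — never silent zeros.

# Known limitations

* No recombination within 5-kb segments; window trees therefore change
  only at segment boundaries, which slightly understates between-window
  heterogeneity relative to real data.
* The permutation test's conservativeness at small region sizes is
  intrinsic to discrete block shuffling, not a bug; use multi-Mb regions.
* The trend-test GWA stand-in does not correct for relatedness or
  structure; its role is to feed realistic p-values to the
  post-processing, not to replace a mixed model.
* `classify_transpoly` and all frequency statistics assume biallelic
  input; the multiallelic dialect exists only for the genealogy stage.
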