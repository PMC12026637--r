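---
title: "popdiff: methods, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{popdiff: methods, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

popdiff implements the classical diversity-and-differentiation workflow for
small panels of biallelic SNPs genotyped across many populations. This
vignette records the estimators, their assumptions, and the choices made
where more than one defensible convention exists.

```{r setup}
library(popdiff)
```

## Data model

Genotypes are stored as alt-allele dosages (0 = ref/ref, 1 = het,
2 = alt/alt) with an explicit `NA` for missing calls. Every statistic is
computed on the *typed* sample size at each (population, locus) cell,
never on the nominal population size: with PCR-based genotyping, per-locus
missingness is the rule rather than the exception, and typed-n is the only
convention under which published per-locus tables can be reproduced from
frequencies. Coordinates are 1-based; VCF input is restricted to biallelic
SNP records (others are skipped with a warning).

The package ships the 11-population, five-locus water-buffalo panel as a
frequency preset (`study_frequencies()`, `study_preset()`). The preset
uses the per-population sizes printed with the frequency table (BGD = 45,
total 917); the sampling-section counts (BGD = 46, total 918) are available
via `sizes = "methods"` because the two published accounts differ by one
Bangladeshi animal. Population codes follow the result tables ("BGD").

## Within-population diversity

* **Allele frequency**: `p = (2 n_refref + n_het) / (2 n_typed)`.
* **Observed heterozygosity**: `Ho = n_het / n_typed`.
* **Expected heterozygosity** uses Nei's unbiased small-sample correction
  `He = (2n/(2n-1)) (1 - p^2 - q^2)`. The correction matters: at the
  panel's sample sizes it shifts the third decimal, and it is the form that
  reproduces the published gene-diversity cells (e.g. p = 0.822, n = 45
  gives 0.296; p = 0.990, n = 149 gives 0.020).
* **Fis** defaults to `1 - Ho/He` with He unbiased. The Weir-Cockerham
  within-population `f` (the variance-components form at r = 1, as FSTAT
  reports) is available via `fis_mode = "wc"`. Published per-locus Fis
  tables rarely state which of the two was used; the two agree to ~0.02 at
  n of a few dozen, so printed values are matched within tolerance rather
  than exactly.
* **Hardy-Weinberg test**: the three-genotype-class chi-square against
  expectations from the sample frequency, df = 1, no continuity
  correction, no exact test — the published tables report plain chi-square
  values. A monomorphic cell has no test; it is `NA` in code and rendered
  "-" in formatted tables. Deviation counts report `k` significant tests
  out of `m` = populations x loci, *including* undefined cells in `m`
  (the convention behind "5 of 55 = 9.09%" style statements).
* **Population means** over the locus panel are unweighted and count
  monomorphic loci as zeros — required to reproduce published means such as
  0.074 for populations monomorphic at three or four of five loci.

The chi-square approximation is checked empirically in the test suite: at
n = 200 under equilibrium the type-I error at alpha = 0.05 stays within
three binomial standard errors of 0.05 over 2000 replicates. At the small
end (n = 15 populations) the approximation is cruder; the package follows
the published choice of test regardless.

## Between-population differentiation

The headline estimator is Weir & Cockerham's theta, computed from the
standard per-locus variance components `a` (among populations), `b` (among
individuals within populations) and `c` (within individuals), with the
multilocus value `sum(a) / sum(a+b+c)`. Theta is preferred because it
corrects for unequal and small sample sizes, may legitimately be slightly
negative in the absence of differentiation (bias O(1/n)), and is what
FSTAT-era studies actually computed. Loci monomorphic across the included
populations (or within a pair, for pairwise values) drop out of the sums.

Nei's `G_ST = (H_T - H_S)/H_T` is provided as a frequency-only secondary
estimator with two weightings. On the packaged buffalo panel the
sample-size-weighted form gives

```{r}
round(nei_gst(study_frequencies(), "by_n")$gst, 4)
```

which matches the study's published global value (0.2143) to about 0.1% —
the small residual being consistent with the panel's frequencies printed at
3 decimals. The equal-weight form gives ~0.239. Both are exposed and
labelled; "global F_ST" in older reports can mean either.

Permutation significance permutes *individuals* among populations (keeping
within-individual allele pairing, hence Ho structure, intact), with
`p = (1 + k)/(B + 1)`. For two populations of a few individuals the
distinct relabellings are enumerated exhaustively (`B = "exhaustive"`) and
the p-value is exact. Multiple testing across population pairs uses the
Holm step-down (sequential Bonferroni) via `stats::p.adjust`; raw and
adjusted p-values are both reported rather than star codes, since published
star legends are often internally inconsistent.

The buffalo-type heterogeneity test is a per-locus 2 x g contingency
chi-square on allele counts (df = g - 1). The study's per-type chi-square
values (352.52, 324.19) depend on per-type allele counts that were never
published alongside the per-population tables, so the operation is
exercised on synthetic three-type data instead.

### Calibration

Because the study's individual genotypes are not deposited, the estimators
are calibrated against the Balding-Nichols model, where population
frequencies are Beta-distributed around an ancestral frequency with
variance `F p (1 - p)`. The acceptance suite simulates 10 populations x 50
loci x 100 individuals for F in {0.05, 0.2} and requires the multilocus
theta to recover F within 25% relative error averaged over 20 replicates.
These sizes keep the check under a minute while leaving the Monte-Carlo
error well below the tolerance.

## Distances and trees

Nei's standard distance uses gene identities `J_x`, `J_y`, `J_xy` averaged
over loci, `D = -ln(J_xy / sqrt(J_x J_y))`. Populations fixed for opposite
alleles at every shared locus have infinite D; tree building requires
capping (`cap_distances()`, default ceiling twice the largest finite
entry), and the capping is warned about, never silent.

Trees come from `stats::hclust`: UPGMA (= "average"), complete linkage, and
Ward ("ward.D2", the Lance-Williams recurrence on squared dissimilarities).
The test suite checks all three against a naive O(n^3) re-implementation of
the Lance-Williams updates. UPGMA trees are ultrametric by construction;
tip branch lengths are half the merge height.

Uncertainty is attached by resampling *loci* with replacement: each
replicate recomputes the distance matrix and tree, supports are the
percentage of replicates containing each clade of the full-data tree
(`ape::prop.clades`), and the consensus is majority-rule (> 50%,
`ape::consensus`). The study describes "100 permutations" for its
distances; a permutation scheme for a distance statistic is undefined, so
popdiff interprets the resampling as a locus bootstrap — the only
resampling unit available to a 5-locus study — and documents that
interpretation here. With five loci, supports are coarse (resolution ~ the
number of distinct resamples); that is a property of the design, not the
implementation.

On the packaged panel, the UPGMA tree of Nei distances groups the three
swamp-type populations {CHN, VNM, IDN} as an exact clade. The South-Asian
river group {BGD, NPL, PAK} forms a contiguous block that additionally
contains IRN — unsurprising given the panel's smallest pairwise
differentiation sits between IRN and PAK. The packaged topology check
(`is_tree_group()`) therefore tests *non-interleaving* (the smallest clade
containing one trio excludes the other trio) rather than strict monophyly,
which matches the qualitative published description of the clades.

## Ordination and clustering

Genotype PCA mean-imputes missing dosages per locus, centers columns
(scaling optional, off by default — dosages share a scale), and reports
orthonormal loadings and variance fractions summing to one. Group ellipses
are the 2-df chi-square 0.95 scaling of per-group score covariance.

"PCA of a distance matrix" is ambiguous in the literature; popdiff defaults
to treating matrix rows as feature vectors (the literal reading) and offers
classical PCoA (double-centered `-d^2/2`) as `mode = "pcoa"`. Both report
variance fractions so either interpretation of a published figure can be
reproduced.

k-means is Lloyd's algorithm (`stats::kmeans`) with 10 seeded random
restarts by default; empty-cluster warnings from individual restarts are
muffled because the best restart is kept. Model selection over K = 2..7
(the wider of the two ranges the study mentions) maximizes the mean
silhouette, ties broken by the smaller Davies-Bouldin index. Both indices
are implemented from their definitions; silhouette gives singleton clusters
a score of 0, and the Davies-Bouldin index is *unbounded above* —
descriptions claiming a 0-1 range are incorrect, and coincident centroids
yield Inf with a warning. Published values such as SS = 0.465 / DBI = 0.268
at K = 6 depend on undocumented PCA mode, seeds and restarts, and are
treated as qualitative; the package instead validates K-selection on
planted Gaussian blobs (>= 5 sigma separation, K = 3..6, >= 95% recovery
over 20 seeded replicates).

## Synthetic generator

`generate_genotypes()` draws genotypes from
`(p^2 + Fpq, 2pq(1-F), q^2 + Fpq)` per population x locus, so `F = 0` gives
Hardy-Weinberg proportions and `F = 1` no heterozygotes, then masks calls
at `missing_rate`. Random streams are split per (population, locus) —
editing one population's spec never perturbs another's draws. The preset
defaults *are* the study design (11 populations, published frequencies and
sizes, F = 0, no missingness); the generator emulates allele-frequency
structure only. It deliberately omits linkage disequilibrium (the five
study SNPs span four chromosomes; the two casein SNPs' physical linkage is
ignored, as in the study), genotyping error, and within-population
substructure — so passing recovery tests demonstrate estimator
correctness, not robustness to those real-data features.

`reconstruct_counts()` inverts a published (p, n, He, Fis) cell into an
integer genotype triple: the heterozygote count is `round((1-Fis) He n)`
(ties toward fewer heterozygotes), the reference-allele count `round(2np)`,
and parity between them is restored by moving the heterozygote count,
preferring fewer heterozygotes. Validation tolerances acknowledge integer
granularity: the recomputed frequency must sit within
`max(0.001, 0.25/n)` of the input and Ho within `0.015 + 1.5/n` — at
n = 50 a parity adjustment alone moves Ho by 0.02, so a flat 0.015 would
reject triples that are in fact the unique consistent inversion. Published
tables are only partially invertible: a few cells are mutually
inconsistent at the printed n (presumably reflecting unreported per-locus
missingness), and those are excluded from exact round-trip tests.

## Reproducibility conventions

Every stochastic operation takes an explicit seed; nothing seeds from the
wall clock. `run_pipeline()` derives fixed offsets from its master seed for
the permutation, bootstrap and k-means stages and records them in
`run_metadata.json`, so a configuration reruns byte-identically. Test-suite
problem sizes (2000 Hardy-Weinberg null replicates at n = 200, 1000
Fis replicates at n = 500, 20 Balding-Nichols replicates at 10 x 50 x 100,
60-1000 tree bootstraps) were chosen to keep Monte-Carlo error a few-fold
below each tolerance while the whole suite runs in about a minute.

## Known limitations

* Biallelic loci only; no multi-allelic gene-diversity or distance
  formulas, no rarefaction or allelic richness.
* No AMOVA or hierarchical F-statistics; no haplotype or linkage-aware
  statistics.
* The Hardy-Weinberg test is asymptotic; for very small or very skewed
  samples an exact test would behave better, but would not match the
  published chi-square values.
* Locus-bootstrap supports from a five-locus panel are necessarily coarse.
* The exhaustive permutation mode enumerates two-population relabellings
  only; three-or-more-population exact tests grow combinatorially and are
  not attempted.
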