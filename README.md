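# popdiff

Population-genetics analysis for *sparse* SNP panels: a handful of biallelic
markers typed across many populations, as is typical for gene-targeted
diversity studies in livestock. The package was built around an
11-population water-buffalo (*Bubalus bubalis*) survey of five dairy-trait
SNPs (in *LPL*, *CSN1S1*, *CSN3*, *DGAT1* and *SCD*), which it ships as a
frequency preset, but every function takes ordinary genotype or frequency
tables.

## What it computes

**Within populations** — allele frequencies, minor allele frequency, observed
heterozygosity *H*<sub>O</sub>, Nei's unbiased gene diversity

&nbsp;&nbsp;&nbsp;&nbsp;*H*<sub>E</sub> = (2*n* / (2*n* − 1)) · (1 − *p*² − *q*²),

Wright's *F*<sub>IS</sub> = 1 − *H*<sub>O</sub>/*H*<sub>E</sub> (or the
Weir–Cockerham within-population *f*), and the three-class Hardy–Weinberg
χ² test (df = 1).

**Between populations** — the Weir–Cockerham variance-components estimator θ
of *F*<sub>ST</sub> (global, per locus, and pairwise), with permutation
significance (individual relabelling; exhaustive enumeration on tiny
instances) and sequential Bonferroni (Holm) correction; Nei's
*G*<sub>ST</sub> = (*H*<sub>T</sub> − *H*<sub>S</sub>)/*H*<sub>T</sub>
as a frequency-only alternative; and a per-locus allele-count heterogeneity
χ² across groups (e.g. river vs swamp vs wild buffalo).

**Structure** — Nei's standard genetic distance *D* = −ln *I*, agglomerative
trees (UPGMA, complete linkage, Ward) with locus-bootstrap support and
majority-rule consensus, Newick export via `ape`; PCA of genotype dosages
(with 95% group ellipses) and of distance matrices (row-feature PCA or
classical PCoA); seeded k-means over a range of K scored by the mean
silhouette and the Davies–Bouldin index.

**Synthetic data** — a generator drawing genotypes from
(*p*² + *Fpq*, 2*pq*(1 − *F*), *q*² + *Fpq*) per population and locus,
Balding–Nichols differentiated frequencies
(*p*<sub>i</sub> ~ Beta with mean *p* and variance *F p q*) for calibrating
the *F*<sub>ST</sub> estimators, and `reconstruct_counts()` to invert
published (*p*, *n*, *H*<sub>E</sub>, *F*<sub>IS</sub>) summaries into
integer genotype counts.

## Worked example

```r
library(popdiff)

# the published 11-population x 5-locus frequency panel
sf <- study_frequencies()
nei_gst(sf)$gst
#> [1] 0.2146162   # global G_ST: ~21% of diversity lies between populations

# simulate genotypes under the published design, then run everything
g <- generate_genotypes(study_preset(), seed = 42)
bundle <- run_pipeline(g, "results_run", B_perm = 100, n_boot = 1000, seed = 42)
report_summary(bundle)
#> popdiff pipeline summary (seed 42)
#> global Weir-Cockerham theta: 0.2407
#> global Nei G_ST (by_n): 0.2179
#> lowest pairwise theta: -0.0085 (IDN-VNM)
#> highest pairwise theta: 0.6856 (EGY-IDN)
#> lowest pooled MAF: 0.115 (SCD_g.21066603C>A)
#> HWE deviations: 1 of 55 tests (1.82%)
#> chosen K: 2 (silhouette 0.669, DBI 0.329)
#> highest |loading| on PC1: LPL_g.129635007G>A
#> highest |loading| on PC2: LPL_g.129635007G>A
```

Reading the digest: about 24% of the simulated genetic variance lies between
populations (θ = 0.24); the Egyptian–Indonesian pair is the most
differentiated (θ = 0.69) while Indonesia–Vietnam are nearly
indistinguishable (θ ≈ 0, slightly negative as the unbiased estimator
allows); the rarest pooled minor allele is the *SCD* promoter C; and one of
the 55 population × locus Hardy–Weinberg tests deviates at α = 0.05 — the
expected false-positive count under equilibrium, since the generator draws
HWE genotypes. `run_pipeline()` also leaves TSV/JSON/Newick artifacts
(frequency, heterozygosity, pairwise-θ and validity tables, PCA scores,
trees with bootstrap supports) in the output directory.

A thin command-line wrapper ships in `inst/cli/popdiff.R`:

```sh
Rscript inst/cli/popdiff.R simulate --preset study --seed 1 --out geno.tsv
Rscript inst/cli/popdiff.R run --input geno.tsv --out-dir results/
```

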