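---
title: "Methods: comparative Pool-seq genome scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative Pool-seq genome scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(poolscan)
```

`poolscan` analyses pooled whole-genome sequencing of population pairs
sampled across a latitudinal contrast in several species, and asks two
questions: which genes show unusually strong allele-frequency
differentiation within a species (local adaptation), and whether the same
orthologous genes are differentiated in a second species (convergent
evolution). This vignette explains the statistical model behind each
stage, the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the numerical choices made where
the design was genuinely open.

## Data model

The atom is a biallelic site with per-pool ref/alt read counts, carried as
a long tibble (one row per site × pool). Genotype calls are never used:
with pooled libraries the allele frequency estimate is the read fraction
`p = alt / (ref + alt)`, and every downstream statistic must account for
the two-stage sampling that produced it — first `2N` allele copies drawn
into the pool from the population, then reads drawn from the pool. Pool
metadata therefore records the number of diploids per pool (`ploidy =
2N`) and each pool's side of the north/south contrast. All internal
coordinates are 0-based half-open; VCF (1-based) and GFF3 (1-based
closed) are converted at the boundary so window and gene interval
arithmetic is uniform.

## SNP filtering

Variant tables are filtered after calling with the standard Pool-seq
thresholds, all configurable in `filter_config()`: drop multiallelic
sites; total coverage (summed over the species' pools) ≥ 50 reads, so
that with pools of ~25–50 diploids each chromosome is expected to be seen
at least once; site quality ≥ 20; pooled minor-allele frequency ≥ 0.01;
and ≥ 2 reads supporting the minor allele. The minor-allele rules are
computed on counts summed across the species' pools, matching the
multi-sample mpileup view a pooled caller sees; a stricter per-pool
coverage mode is available (`per_pool_coverage = TRUE`) because it is
genuinely ambiguous whether a coverage floor should bind each pool or the
combined sample — the combined reading is the default since the floor's
rationale (every individual represented) concerns the species-wide
sample. Sites failing several rules are attributed to the first failing
rule in the fixed order multiallelic → coverage → quality → maf →
min-minor-reads, making the removal report deterministic and the counts
conserve exactly (input = removed + passed).

## Windowed expected heterozygosity

Per-pool diversity is the average expected heterozygosity of *all* sites
in a fixed window (default 50,000 bp), with invariant sites contributing
zero: the window score is `sum(2p(1-p) over SNPs) / window_length`.
Dividing by window length rather than SNP count makes windows with
different SNP densities comparable and gives scores of order 10⁻³. The
plug-in read frequency is used without a depth correction — windowed
averages of `2p(1-p)` are nearly unbiased in depth across realistic
coverages, and no correction is applied so that the statistic stays
exactly the simple average it claims to be. Windows tile each chromosome
from position 0; the trailing partial window uses its actual length as
denominator, so the conservation identity `sum(window score × window
length) = sum(per-SNP H_E)` holds exactly (it is asserted in the tests
over random layouts). An optional callable-site mask (BED-like intervals)
replaces the denominator by callable bases; by default no mask is used
because the window definition deliberately counts all sites.

## Pool-corrected FST

The per-SNP estimator is an ANOVA (method-of-moments) estimator built on
identity-in-state (IIS) probabilities, in the class of estimators
designed for Pool-seq. Two reads drawn without replacement from a pool of
haploid size `n` come from the same chromosome with probability `1/n`, so
the read-level IIS overestimates the population-level within-pool
identity; inverting that relation gives the unbiased `Q1 = (n·IIS − 1) /
(n − 1)`. Between pools reads are always from different chromosomes, so
`Q2` is the plain cross-pool IIS. Then `FST = (Q1 − Q2)/(1 − Q2)` per
SNP, averaging `Q1` over the two pools. Sites where either pool has fewer
than 2 reads, or where both pools are fixed for the same allele
(denominator zero), are missing. Negative per-SNP values are retained —
they are an estimator property under no differentiation, and clamping
would bias the outlier quantile upward.

Two numerical points matter:

- **Genome-wide FST is a ratio of sums**, `Σ(Q1 − Q2)/Σ(1 − Q2)`, not the
  mean of per-SNP ratios. The per-SNP denominator is itself noisy, and
  averaging ratios is biased towards zero (severely so at high
  differentiation: simulation at F = 0.49 gives a per-SNP mean near 0.31
  but a ratio-of-sums estimate within 0.005 of truth). `genomewide_fst()`
  reports both, and the tests assert recovery of the simulated F at
  ±0.02 across F ∈ {0.02, 0.12, 0.14, 0.49}.
- **The pool correction is what buys depth invariance.** A depth-corrected
  Hudson estimator on read frequencies (`estimator = "hudson"`) is kept
  as an independent cross-check; it corrects read-sampling noise but not
  the individual-sampling stage, so it converges with the ANOVA estimator
  only when depth and pool size are both large. A naive plug-in on read
  frequencies is inflated at low depth; the test suite demonstrates both
  behaviours on seeded simulations.

For species with more than two pools, FST is computed for designated
north–south pool pairs only (all north × south combinations by default,
explicit pairs accepted), since the latitudinal contrast is the axis of
interest.

## Gene-level aggregation and ortholog filtering

Gene FST is the arithmetic mean of the per-SNP values inside the gene
interval; genes without SNPs carry missing means rather than zeros.
Windowed heterozygosity cannot be computed per gene (windows are much
wider than genes), so each gene inherits the score of the window it
overlaps most, with an exact 50/50 split resolved to the left
(lower-coordinate) window. Neighbouring genes therefore share window
scores — accepted pseudoreplication that can only overstate the
significance of a true cross-species correlation, making null results
conservative.

Ortholog tables (a pipeline input, with mapping quality, percent identity
and relation class per pair) are filtered in a fixed order: quality first
(mapping quality ≥ 80 and identity ≥ 90%), then removal of every pair
whose gene still occurs in more than one surviving pair (judged
simultaneously on the quality-surviving set, eliminating 1:many and
many:many relations), then removal of pairs whose gene interval overlaps
another gene in its own species (any base-pair overlap — the simplest
testable reading). Quality-before-multiplicity maximises retained 1:1
pairs: a 1:many relation whose spurious branch fails the quality filter
is rescued as 1:1. The output is a bijection, asserted in tests.

## The top-candidate test

Within a species, outlier SNPs are those strictly above the empirical
0.999 quantile of all per-SNP FST values. Quantiles use the nearest-rank
rule (the `⌈nq⌉`-th order statistic, R's type-1): with 1000 distinct
values the threshold is the 999th order statistic and exactly one SNP
exceeds it. Strict exceedance is used for both the SNP rule and the gene
rule, symmetric by design. A gene with `n` SNPs is a top candidate iff
its outlier count strictly exceeds `qbinom(0.999, n, 0.001)` — the
0.999 quantile of the binomial null in which each SNP is independently an
outlier with probability 0.001. The success probability is fixed at
0.001 rather than the realised outlier fraction, keeping the null
interpretable as "what 0.1% tails would do by chance". SNPs with missing
FST count toward neither `n` nor the outlier count. Under a neutral
simulation the candidate rate stays below 0.002, and planted genes at 4×
baseline differentiation with ≥ 20 SNPs are recovered with sensitivity
above 0.8 (both asserted in the acceptance tests).

## The Null-W test

Direction is explicit: candidates are identified in species A and
divergence is evaluated in species B. One shared control set — 10,000
SNPs sampled uniformly without replacement from B's non-missing per-SNP
FST values, fixed by the run seed — anchors every comparison. For each
test gene (a B-ortholog of an A-candidate with at least
`min_snps_per_gene` SNPs) the Mann–Whitney U of its SNPs against the
controls is standardised to `Z = (W − n₁n₂/2)/√var` with the standard
tie-corrected variance and no continuity correction; the Z values of the
null genes — by default *all* non-candidate orthologous genes, a
deterministic choice; a `random_k` subsample is available — form the
reference distribution. The empirical p-value is the add-one position
estimator `(1 + #{null Z ≥ test Z})/(1 + N_null)`, which can never be
zero, one-sided because elevated FST in B is the signal. Bonferroni
correction over the number of test genes controls the family-wise error.

Two consequences are worth knowing. First, the smallest attainable
adjusted p is `n_test/(N_null + 1)`: large candidate sets with modest
null sets cannot reach significance at all, which makes the test
conservative by construction. Second, because all genes share one control
set, p-values of different genes are dependent; calibration is therefore
checked on pooled empirical p-values across independent replicates
(Kolmogorov–Smirnov distance to Uniform(0,1) below 0.1, and zero
Bonferroni-significant calls in at least 18 of 20 replicates with no
convergent selection planted). For those calibration runs selection is
planted in species A only — a fully neutral A would have essentially no
candidates and hence no test set to calibrate on — and the candidate set
is taken from the generator's truth labels so the check isolates the
Null-W machinery from top-candidate detection noise. Power is assessed
with convergent genes planted in both species at a strong effect
(elevated F = 0.7 against baselines of 0.12–0.14): planted orthologs with
≥ 20 scored SNPs are Bonferroni-significant in over 80% of cases.

## Cross-species comparisons

Gene-level Spearman correlations (midranks, large-sample t approximation
for p) are computed over matched 1:1 ortholog scores, with per-gene
heterozygosity averaged across each species' populations first. The
population × population H̄E correlation matrix uses windows directly
within a species; across species, windows are not homologous, so each
species' window scores are projected onto genes (via the window-majority
assignment above) and populations are compared over ortholog-linked
genes — the only projection consistent with how gene scores are defined.
Shared-extreme counts use per-species nearest-rank quantile thresholds
(0.95/0.05 by default) over the matched set, counting genes strictly
beyond both species' thresholds.

## The synthetic-data generator

`simulate_species()` draws, per SNP, an ancestral frequency p₀ ~
Uniform(0.05, 0.95); each population's frequency from the
Balding–Nichols Beta(p₀(1−F)/F, (1−p₀)(1−F)/F), so the across-population
variance is F·p₀(1−p₀); then `2N` allele copies binomially and reads
binomially at Poisson depth. The two-stage sampling is the point: it
reproduces exactly the noise structure that motivates the pool-corrected
estimator, and the tests demonstrate the correction's advantage on it.
Site qualities are Uniform(15, 60) so a realistic minority of sites fail
the quality filter. Genes are placed without overlap (evenly spaced
slots with jitter); SNPs inside selected genes are drawn at
`elevated_fst` instead of the baseline. `simulate_species_pair()` builds
a shared gene catalogue, an ortholog map with configurable 1:many
fraction, truncated-normal identity and a low-mapping-quality fraction
(so the ortholog filter has real work), and plants convergent genes —
elevated in both species — only among pairs that survive the ortholog
filter, since a convergent gene whose ortholog link is discarded could
never be tested.

The three named presets reproduce the qualitative regimes of the
sticklebacks-and-allies study system the package targets: a
`threespine`-like species (pools of 52/51 diploids, baseline F = 0.14), a
`tubesnout`-like one (44/50, F = 0.12) and a bottlenecked
`ninespine`-like one (four pools, F = 0.49), each sequenced at target
depth 2N (one read per chromosome in expectation). Desk-scale defaults
(two chromosomes, 10⁴–10⁵ SNPs) keep every test and the acceptance script
in minutes; the vignette's problem sizes are the package's own choice of
what is convincing at desk scale.

What the generator does **not** emulate: linkage (SNPs are independent,
so there are no genomic islands and no clustering of outliers beyond
genes), mutation-model detail (no invariant-site genotyping error, no
multiallelic sites by default), reference bias, and the demographic
history behind a bottleneck — the ninespine-like preset raises F but
keeps the ancestral frequency distribution, so its heterozygosity drops
only ~40% rather than the ~10× a real bottleneck produces. Passing tests
therefore demonstrate the statistics are computed correctly and are
calibrated under the stated model, not that the model captures every
feature of real Pool-seq data.

## Pipeline orchestration and reproducibility

`run_pipeline()` drives the full two-species analysis from one YAML (or
list) config — simulated or on-disk inputs — writing provenance-stamped
TSVs (every writer emits a comment line with package version and
parameters) and a `manifest.json` with per-stage counts that satisfy
conservation identities. All randomness derives from the single config
seed, so reruns are byte-identical apart from the manifest timestamp.
The spec-style per-stage command lines are deliberately not shipped as
shell executables: this is an analysis library, and the exported
functions plus `run_pipeline()` are its interface.

## Known limitations

- Per-SNP FST estimates are individually noisy; gene means over few SNPs
  inherit that noise, and the top-candidate test's binomial null ignores
  LD (none is simulated, but real data has it — the original
  top-candidate literature treats clustered outliers accordingly).
- With the all-noncandidate null-gene default, Null-W significance is
  unattainable when the candidate set is large relative to the ortholog
  catalogue (smallest adjusted p is `n_test/(N_null+1)`); use `random_k`
  or interpret ranks directly in that regime.
- The window-majority heterozygosity assignment pseudoreplicates
  neighbouring genes; correlations among gene H̄E values are therefore
  anti-conservative and are reported as computed, without correction.
- `quantile_threshold()` is nearest-rank by design; other interpolation
  rules shift outlier counts by at most one rank but would break the
  exact "one-in-a-thousand" reading used throughout.
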