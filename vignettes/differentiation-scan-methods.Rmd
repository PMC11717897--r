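---
title: "Methods: windowed differentiation scans for partial migration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed differentiation scans for partial migration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each choice, and what the synthetic cohorts do and do
not establish about real data.

## The question and the design

In a partially migratory population, migratory and resident individuals
breed side by side. If migratory behavior has a polygenic or haplotype
basis, some genomic regions should differentiate the two phenotype groups
beyond what shared population processes (drift, background selection,
variable recombination) produce everywhere. The scan therefore always
runs **two** comparisons on the same window grid:

* a *focal* between-phenotype comparison inside the panmictic focal
  population (no population structure separates the groups, so any
  consistent signal is phenotype-associated), and
* a *control* within-phenotype comparison between two geographically
  separated populations of the same phenotype, which captures the
  baseline heterogeneity of the differentiation landscape.

Both are Z-normalized per scaffold and subtracted per orthologous window
(`delta_fst_prime()`): ΔF~ST~′ = F~ST~′(focal) − F~ST~′(control). The
direction is *between-phenotype minus control*, so high ΔF~ST~′ means
phenotype-associated differentiation.

## Estimators

**Window statistics** (`window_stats()`). Windows tile every scaffold
from position 1 in non-overlapping 2.5 kb steps; window *k* covers
`[2500k+1, 2500(k+1)]`; the trailing partial window is kept. Within a
window, per-site π = 2p(1−p)·n/(n−1) (n = non-missing allele copies) and
D~xy~ = p₁(1−p₂)+p₂(1−p₁) are averaged over the variant sites with
defined frequencies in both groups, and Hudson's F~ST~ is the
ratio-of-averages `1 − ((π₁+π₂)/2)/D̄xy` — not the average of per-site
ratios, which is noisier and biased. A window is *missing* when it has
fewer than 10 usable SNVs or D̄xy = 0. Negative F~ST~ values are kept:
clamping at zero would distort the Z-scores that everything downstream
consumes. Because the input VCF carries variant sites only, π and D~xy~
are per-variant-site quantities; their ratio (the only thing F~ST~ uses)
is unaffected by the missing invariant sites.

A consequence of the unbiased π worth knowing: if the *same* samples are
used as both groups, π̄ = D̄xy·n/(n−1) exactly, so F~ST~ = −1/(n−1)
rather than 0. The estimator is centered on zero only across independent
samples; the test suite pins both properties.

**Per-SNV Weir–Cockerham θ̂** (`per_snv_fst_wc()`): the 1984
variance-components estimator for two groups, with observed heterozygote
proportions, vectorized over sites; monomorphic sites return missing and
negative estimates are retained. An independently written scalar
transcription of the 1984 equations serves as the oracle in tests.

**Tajima's D** (`window_tajima_d` inside `window_stats()`): computed per
group per window from S (sites segregating *within that group*) and the
summed per-site π, with the Watterson constants for n = 2m nominal
sequences. Missing genotypes enter through the missing-aware per-site
frequencies while n stays nominal — a documented simplification that is
accurate at the few-percent missingness the filters allow through.

**Z-normalization** (`z_normalize_per_scaffold()`): sample SD (n−1
denominator) over the scaffold's non-missing windows; scaffolds with
fewer than two non-missing windows or zero SD produce all-missing scores
with a warning. Normalization is per scaffold, not pooled, so
scaffold-scale differences in diversity and recombination do not leak
into the outlier threshold.

**Outliers and clusters** (`call_outliers()`, `call_clusters()`): the
threshold is the genome-wide 99th percentile (type-7, linear
interpolation — the convention R users will reproduce by default) of
non-missing ΔF~ST~′; flags are *strictly above*. A cluster is a maximal
run of ≥ 5 outlier windows within one scaffold where missing windows are
skipped — they neither break nor lengthen the run — and background
windows break it. The caller is verified against an exhaustive oracle
over every flag string of length ≤ 12 (3^12 strings and all shorter).

**Kruskal–Wallis contrasts** (`compare_cluster_tajimas_d()`): cluster
windows' D against the genome-wide distribution, via
`stats::kruskal.test`; p-values are reported raw — the scan applies no
multiple-testing correction anywhere, so its outputs are descriptive
rankings, not calibrated significance statements.

## Filter chain

`filter_chain()` fixes the order: site QC → genotype masking →
individual removal → missingness → repeat mask.

* Site QC: QUAL > 20 (strict), INFO DP strictly between the sample count
  and 2× the mean INFO DP (mean over the *pre-filter* site set), MQ > 30
  (strict), RPBZ in [−3, 3] (inclusive — "between" read inclusively, and
  documented here because either reading is defensible).
* Genotypes with per-sample DP < 4 become missing; DP = 4 survives.
* Individuals below half the across-individual mean depth are removed;
  the mean is computed before any removal so exclusions do not cascade.
* Sites with **more than** 20% missing genotypes among the retained
  individuals are removed (recomputed after masking and individual
  removal).
* BED intervals are 0-based half-open against 1-based sites: position P
  is masked iff some interval [s, e) has s ≤ P−1 < e.

The site-level "read depth of more than the total number of samples" is
interpreted as INFO DP > number of VCF samples — the only
sample-count-scaled depth quantity available per site.

## Kinship, PCA, LD, inversion detection

**Kinship** (`kinship_mom()`): PLINK-style Method-of-Moments IBD from
observed IBS(0/1/2) counts. Three design points matter in practice:

1. the conditional IBS-class expectations use *unbiased falling-factorial
   estimators* of the frequency monomials (p²q², p³q, …) from allele
   counts, not plug-in powers of p̂ — the plug-in version inflates
   kinship noticeably at these sample sizes;
2. sites below MAF 0.05 are excluded: near-fixed variants carry almost
   no IBD information and destabilize the moments, especially under the
   growth-skewed spectra this cohort design assumes;
3. the pipeline prunes LD first (`ld_prune()`, 50-SNV windows, step 5,
   r² > 0.2). Without pruning, a segregating inversion contributes
   thousands of perfectly correlated sites that all report the same IBS
   event, and unrelated pairs drift far above the 0.1 exclusion
   threshold. This mirrors standard practice for moment-based
   relatedness tools.

Estimates are truncated to [0, 1] and renormalized; φ = k₂/2 + k₁/4.
The exclusion rule (`apply_relatedness_exclusion()`) processes pairs in
descending φ and removes the lower-depth member; depth ties fall back to
the lexicographically smaller id (logged), so the rule is deterministic.

**PCA** (`pca_genotypes()`): sites standardized by `(g − 2p̂)/√(2p̂(1−p̂))`,
missing dosages mean-imputed (0 after centering), eigendecomposition of
the sample×sample covariance. Mean imputation was chosen over
pairwise-complete covariance, which is not guaranteed positive
semi-definite.

**LD** (`ld_r2()`): composite r² — squared Pearson correlation of
unphased dosages over pairwise-complete samples — because genotypes are
unphased; pairs with fewer than 4 complete observations are masked. For
matrix-scale summaries sites are thinned to an evenly spaced subset
(default cap 400) rather than sampled, keeping every output
deterministic.

**Inversion detector** (`detect_inversion_signature()`): a scaffold is
called when three conditions hold jointly — (i) the scaffold-restricted
PC1 splits into three separated clusters; (ii) the middle cluster has
strictly maximal mean heterozygosity (inversion heterozygotes are
heterozygous across the rearranged block); (iii) mean composite r² on the
scaffold exceeds 3× the genome background (median of the other
scaffolds' means) while the adjacent comparison scaffold stays below it.
The 1-D three-cluster step uses an *exact* 3-means: clusters of sorted
values are contiguous, so both split points are enumerated with prefix
sums. An earlier Lloyd-iteration version (quantile-initialized with
random restarts) converged to a local optimum that split the large
standard-homozygote cluster whenever the three karyotype groups were
very unequal in size — the typical case — which is why the exact,
deterministic partition replaced it. The separation score is the
smallest edge gap between adjacent clusters divided by the PC1 SD; the
0.3 threshold and the 3× LD fold are package constants, exposed as
arguments, chosen once from the null/planted separation of the generator
(null scaffolds score ≲ 0.1, planted inversions ≳ 1).

## The synthetic cohort generator

`sim_config()` / `simulate_cohort()` emulate the study design the scan
is built for; the defaults are the package's reference conditions.

* **Structure**: four populations of 9/7/24/9 diploids drawn from a
  shared ancestral pool under the Balding–Nichols model (population
  frequency ~ Beta with mean p and variance F·p(1−p)). Divergences
  F = 0.06/0.02/0.005/0.005 put the first population clearly apart (PC1)
  and give the control pair an expected Hudson F~ST~ of
  (F₁+F₂)/2 = 0.04, the level of between-population baseline the design
  assumes. The focal population (24) splits into two phenotype groups of
  12; panmixia means both groups share the same frequencies.
* **Spectrum**: ancestral frequencies come from a 99-point grid
  p = i/100 (so all frequencies live in [0.01, 0.99]) with neutral 1/i
  weights; `sfs_skew` multiplies the singleton class. The default of 8
  was set *analytically*: computing the expected sample SFS (grid ×
  binomial sampling) and pushing it through the windowed-D expectation
  gives D ≈ −0.65 at n = 24 sequences and 50 SNVs/window, the
  growth-skewed genome-wide level this design targets; skew 1 gives
  D ≈ +0.08, inside the ±0.3 neutral calibration band (the small
  positive offset is the singleton deficit from truncating the spectrum
  at 0.01).
* **Genome**: five scaffolds of 0.5/0.5/2/1/1 Mb (2000 windows) at
  20 SNVs/kb — the density of a deeply filtered resequencing call set
  (~50 SNVs per 2.5 kb window). The selected-region scaffold is the
  2 Mb one deliberately: Z-normalization uses the scaffold's own SD, so
  a planted region that is a large fraction of a short scaffold inflates
  that SD and suppresses its own Z-scores. At 2.5% of an 800-window
  scaffold the self-inflation is modest and planted windows reach
  ΔF~ST~′ ≈ 4–6 against a background threshold ≈ 3.
* **Selected region**: 50 kb, allele-frequency shift δ = 0.35 applied to
  one phenotype group's sampling frequencies (clipped to [0.02, 0.98]),
  genotypes redrawn binomially.
* **Inversion**: a 500 kb block on its own scaffold; carrier-population
  individuals get a Hardy–Weinberg karyotype at q = 0.5, and every
  marker site in the block is overwritten with the karyotype dosage —
  perfect LD, degraded only by the missingness applied afterwards.
* **Nuisance realism**: 2% random genotype missingness, per-sample
  depths Poisson around per-individual means (optionally a fraction of
  individuals at low depth, below half the cohort mean), QUAL/MQ/RPBZ/DP
  site annotations with ~2% of sites failing each rule, repeat intervals
  covering 5% of each scaffold, and appendable related individuals
  (offspring get one transmitted allele plus one population draw;
  clones copy the parent; both get 0.75× the parent's depth so the
  lower-depth exclusion resolves deterministically).
* **Determinism**: one integer seed drives a single RNG stream;
  identical configs give byte-identical VCF/BED/TSV/JSON output.

**What the generator does not emulate** — and hence what passing tests
do not establish about real data: linkage disequilibrium outside the
inversion block (sites are independent given the frequencies), mutation
and recombination processes along a genealogy (no coalescent), selection
acting over time (the selected region is a static frequency shift),
sequencing error in genotypes, reference bias, and any LD-aware
behavior of real callers' QC annotations (QUAL/MQ/RPBZ are independent
site-level draws). Conclusions about estimator correctness, filter
semantics, cluster logic, kinship moments, and the PCA/LD inversion
geometry transfer; conclusions about genome-wide significance or power
on real LD structure do not.

## Problem sizes and runtime policy

The reference conditions (5 Mb, 100k SNVs, 49–60 individuals) run each
pipeline stage in seconds; the test suite and the acceptance script
re-simulate cohorts at these sizes, use 20k-site single-scaffold
cohorts for the estimator calibrations, and 10 seeds for each
recovery-rate experiment — sizes chosen so the entire verification suite
completes in minutes on one CPU while keeping every rate estimate at a
resolution of 0.1.

## Known limitations

* Tajima's D uses nominal n with missing-aware S and π; at high
  missingness (which the filters are supposed to prevent) D drifts
  toward zero.
* The ΔF~ST~′ contrast inherits the control comparison's sampling noise
  (SD √2 under the null); very short scaffolds normalize poorly and are
  reported missing rather than guessed.
* The inversion detector is a per-scaffold screen with package-constant
  thresholds; it does not localize breakpoints, phase haplotypes, or
  run sliding local PCA, and scaffolds are the unit of assertion — no
  claim is made about chromosome assignment.
* MoM kinship assumes one homogeneous frequency pool; strong structure
  biases φ upward. LD pruning plus the MAF floor keep unrelated pairs
  well below the 0.1 threshold under the reference conditions, but
  cohorts with much deeper structure would need within-group frequency
  estimates or a structure-robust estimator.
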