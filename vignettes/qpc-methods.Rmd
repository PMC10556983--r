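---
title: "Methods: testing expression divergence against neutral drift"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing expression divergence against neutral drift}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpcscan)
```

## The neutral model and the Q~PC~ test

A quantitative trait evolving neutrally in a structured population diverges
between groups in proportion to their relatedness. `qpcscan` operationalizes
this with the conditional-kinship eigendecomposition: from a panel of
putatively neutral SNPs the standardized kinship $K = SS'/L$ is built, with
$s_{il} = (g_{il} - 2p_l)/\sqrt{2p_l(1-p_l)}$ and $p_l$ the alternate-allele
frequency among called genotypes. Mean-centering with $T$ (the first $n-1$
rows of $I - \mathbf{1}\mathbf{1}'/n$) conditions on the trait mean and
gives the rank-$(n-1)$ matrix $K_c = TKT'$, whose eigenvectors $u_m$ are the
axes of population structure and whose eigenvalues $\lambda_m$ measure how
much neutral trait variance each axis should carry.

For a trait vector $z$ the scaled projections
$c_m = u_m' T z / \sqrt{\lambda_m}$ are, under neutrality with additive
variance $V_A$, independent $\mathrm{N}(0, V_A)$ draws. The minor PCs (which
reflect within-cluster relatedness, where selection among clusters cannot
act) provide the estimate $\hat V_A = \mathrm{mean}(c_m^2)$ over the neutral
set, and each major PC is tested with $F = c_m^2/\hat V_A$ against
$F(1, k)$, $k$ the neutral-set size, upper tail only: the question is
*excessive* divergence. The same quantile defines the 95% neutral envelope
drawn by `autoplot()`; envelope exceedance and $p < \alpha$ agree by
construction (this equivalence is asserted in the test suite over hundreds
of simulated traits).

The two traits scanned per gene come from the reaction-norm view of a
two-site reciprocal transplant: the *constitutive* trait is the unweighted
mean of an accession's inland and coastal site means (main effect of
genotype) and the *plastic* trait is the coastal − inland difference
(genotype × environment interaction). Both are mean-centered per gene;
the test is translation invariant, and scaling a trait by $k$ scales
$\hat V_A$ by $k^2$ while leaving $F$ and $p$ unchanged.

Key assumptions: additive trait architecture with covariance proportional to
kinship; a kinship built from neutral, LD-thinned markers; enough neutral
PCs for a stable $\hat V_A$ (`pc_sets()` refuses fewer than three). Selfing
inflates the kinship diagonal (a $(1+F)$-type effect); because both the
trait and the kinship pass through the same centering and the PC basis
absorbs the scaling, the calibration of the test does not depend on an
outbred-population normalization — the type-I error simulations in the test
suite run entirely on selfing genotypes.

## Choosing the PC partition

Two fractions control the partition of the spectrum. `test_fraction = 0.25`
selects the smallest leading block of PCs whose cumulative eigenvalue share
reaches 25% — the broad-structure axes where cluster-level selection would
appear. `neutral_fraction = 0.50` selects the neutral block. The phrase
"PCs explaining cumulatively about half the variance" admits two readings,
and both are implemented:

* `rule = "tail-share"` (default): the smallest trailing block whose summed
  share reaches the fraction. On the toy spectrum $\lambda = (4,3,2,1)$ this
  picks PCs 2–4 (share 0.6).
* `rule = "after-cum"`: every PC after the leading block that reaches
  $1 - \mathrm{neutral\_fraction}$ from the top.

The sets are forced disjoint (the neutral block starts after the test block,
with a warning) since a PC cannot both carry the signal and calibrate the
null. The test-PC *count* is a consequence of the rule, not a parameter: on
spectra with very strong cluster separation the rule picks few PCs, on
diffuse structure more; `max_test_pcs` caps it when a fixed count is wanted.

## q-values

Multiple testing across genes is corrected per tested PC (PCs answer
different questions; pooling is available via `pool_pcs = TRUE`). The
procedure is Storey's: $\hat\pi_0(\lambda) = \Pr(p > \lambda)/(1-\lambda)$
on the grid $\lambda = 0.05, \dots, 0.95$, smoothed with a cubic spline and
evaluated at the largest $\lambda$; estimates above 1, non-finite, or from
fewer than 20 p-values fall back to $\pi_0 = 1$, which makes the q-values
exactly Benjamini–Hochberg (the BH core is `stats::p.adjust`). Outliers are
called at $q < 0.1$.

## Relaxed and constrained modes

Heterochromatic, rarely recombining regions violate the neutral-panel
assumptions in two ways: their SNPs distort the kinship, and their genes sit
on long haplotypes whose expression divergence tracks linked selection. The
*constrained* mode therefore (1) expects a kinship built after
`subset_by_regions(..., mode = "exclude")` purged SNPs outside the
highly-recombined region set — the genotype container carries a provenance
tag and the scan warns on a mismatch — and (2) drops genes whose
representative coordinate falls outside those regions. With regions covering
everything, constrained output equals relaxed output exactly.

## The synthetic-data module

The generator is first-class code: it defines the study conditions under
which the method's operating characteristics are demonstrated.

* **Genotypes** — three genetic clusters of 53, 22 and 11 accessions
  (the design of the emulated field system), 5,000 neutral SNPs at desk
  scale. Cluster allele frequencies follow the Balding–Nichols F-model
  (Beta around a Uniform(0.05, 0.95) ancestral frequency, spread set by a
  per-cluster $F_{ST}$, default 0.25); this is the standard hierarchical
  structure model for a system the source data describe only through
  realized differentiation. Selfing is represented directly at the genotype
  level — individuals are $2\times$Bernoulli homozygotes with a residual 1%
  heterozygous-call rate — because only dosages enter any downstream
  computation; no pedigree is simulated.
* **Traits** — in centered space $z_c = U \Lambda^{1/2} w \sqrt{V_A}$ with
  $w$ standard normal, exactly the null the test assumes; selected traits
  get a mean shift $\delta$ along a chosen eigenvector. Effect sizes are
  free parameters (the source system reports none); the pipeline default
  expresses them as a noncentrality $\delta^2/(V_A \lambda_1) = 16$, which
  puts power in the informative 80–95% range rather than at saturation.
* **Counts** — per accession, site and gene, $\log_2$ mean
  $= \text{baseline} + \text{constitutive} \pm \tfrac12\,\text{plastic} +
  \text{site effect}$, the $\pm\tfrac12$ split chosen so the between-site
  difference of $\log_2$ means equals the plastic trait exactly; counts are
  negative binomial (Poisson at dispersion 0), three replicates per
  accession × site.
* **All-sites windows** and **polarized orthogroups** follow the same
  pattern: known per-population frequencies, plantable fixed differences,
  independent missingness; ancestral states equal the coastal allele with a
  configurable probability.

What the generator does *not* emulate: linkage and recombination (sites are
independent; no LD decay), isolation by distance, sequencing-read noise,
library-composition artifacts beyond a global size factor, and
dispersion–mean trends across genes. Passing tests therefore demonstrate
calibration and recovery under the assumed model, not robustness to
misspecified real data.

## Numerical and convention choices

* Eigenvalues below $10^{-8}\lambda_{\max}$ are clipped to zero and excluded
  from both PC sets; eigenvector signs are fixed (largest-magnitude entry
  positive) so results are reproducible across LAPACK builds.
* Traits are explicitly mean-centered before projection; $T$ annihilates
  constants analytically, and pre-centering keeps constant traits at exactly
  zero projection in floating point ($F = 0$, $p = 1$ rather than a 0/0
  ratio of rounding residues).
* Missing dosages contribute 0 after per-locus centering (mean imputation),
  the convention under which $K$ stays an average of per-locus outer
  products.
* $\hat V_A = 0$ with a nonzero test projection yields $p = 0$ (flagged);
  both zero yields $p = 1$.
* Genotype filters: heterozygosity is a per-site percentage among called
  genotypes (the 3.6% default is the 85th-percentile cutoff used for
  selfing resequencing panels; whether the original filter was per-site or
  genome-wide is not recoverable, so the threshold is a parameter); rules
  attribute drops in the order heterozygosity, missingness, MAC. Two
  presets mirror the two filtering stages: `"variant-calling"`
  (het < 3.6%, missing < 20%) and `"neutral-panel"` (missing < 10%,
  MAC ≥ 3).
* Coordinates: VCF positions are 1-based, regions are BED-style 0-based
  half-open; a site is inside $[s, e)$ iff $\mathrm{pos} - 1 \in [s, e)$,
  making VCF↔BED round-trips lossless. Promoters are the 2 kb upstream of
  the TSS, strand-aware, truncated at the chromosome start.
* The variance-stabilizing step is a started log, $\log_2(x/f + 1)$ on
  median-of-ratios-normalized counts. The trait pipeline needs a monotone
  variance-flattening transform, not a fitted dispersion–mean trend; the
  choice is isolated in `vst_normalize()` so a model-based transform can be
  substituted. Replicates are collapsed *after* the transform.
* π and D~XY~ use the all-sites convention: per-site difference and
  comparison counts (pairs of called alleles) are summed over a window and
  the statistic is the ratio of sums. Missing calls shrink the denominator;
  windows with zero comparisons are `NA`, never 0; adding invariant called
  sites dilutes the statistic by exactly the comparison-count ratio.
  F~ST~ is the Weir–Cockerham (1984) diploid estimator with observed
  heterozygosity (valid at the near-zero heterozygosity of selfers),
  combined as $\sum a / \sum(a+b+c)$; negative window values are reported
  as-is since downstream comparisons use means.
* DAPC is PCA (centered, unscaled — expression is already
  variance-stabilized; a scaling flag exists) followed by Fisher LDA in PC
  space; axes are unit-norm in the whitened within-group metric, singular
  within-group covariance takes a logged $10^{-8}$ ridge, orientation is
  fixed (first group level negative), and posteriors use equal priors with
  the shared whitened covariance. For the expression DAPC the number of
  retained PCs is not dictated by the source design; the pipeline default
  caps at 10 or the sample-size limit, whichever is smaller.
* Plasticity z-transforms discriminant scores within genetic cluster
  (SD with $n-1$), averages replicates per accession × site, and takes the
  absolute transplant − native difference. The cluster effect is tested by
  accession-level one-way ANOVA with Tukey HSD: with replicates collapsed
  to one value per accession, the genotype random effect of a mixed model
  is absorbed into the residual, so the fixed-effect test reduces to this
  ANOVA — a deliberate, documented stand-in.
* Ancestry: orthogroups need ≥ 3 variant sites; only *polarizable* sites
  (exactly one ingroup allele matches the ancestral state) enter the
  fraction — the convention under which "the ancestral ecotype carries more
  ancestral alleles" is well-defined. The per-orthogroup statistic is a
  fraction by default; a majority-call variant is available
  (`method = "majority"`). The CI is a 10,000-replicate percentile
  bootstrap over orthogroups.
* Enrichment: the two-sided exact p sums tables with probability not above
  the observed one (the convention of `fisher.test`, which computes it);
  the odds ratio is the sample $ad/bc$ with a flagged Haldane 0.5
  correction only when a cell is zero.
* Gene-feature statistics feeding the CDE-vs-background comparisons are
  per-gene values (intervals summed before the ratio) entering a one-way
  ANOVA; pooling sites across genes before testing is the other unstated
  possibility and was not adopted, because genes are the unit of replication
  in those comparisons.

## Reproducibility

Every generator takes an explicit seed and runs under a locally scoped RNG
(`withr::with_seed`); no function touches global RNG state. The pipeline
derives per-stage seeds from the run seed, so rerunning a config reproduces
every artifact byte-for-byte — asserted in the test suite by comparing raw
file contents of two runs.

## Problem sizes

The packaged simulations run at desk scale, chosen so the full suite
exercises the study design while staying lightweight: 86 accessions in three
clusters, 5,000-SNP panels (the emulated study used 50,000), 1,000 traits
for calibration checks, 200 genes with 20 planted shifts for power checks,
500-2,000 orthogroups for ancestry, and a reduced `demo_run_config()` for
end-to-end runs. All sizes are config parameters; scaling up changes only
runtime.

## Known limitations

* $\hat V_A$ is a method-of-moments estimate from the neutral PC block, not
  REML; very small neutral sets make it noisy (hence the ≥ 3 PC floor).
* The test is one-sided for excessive divergence; stabilizing selection
  (too-little divergence) is out of scope.
* Independence of sites in the simulators means realized $F_{ST}$ standard
  errors are optimistic relative to linked real data.
* The started-log transform flattens variance less well than a fitted
  dispersion–mean VST for very low counts; low-expression filtering
  (mean count < 1 removed) limits the impact.
* `compare_gene_sets()` assumes per-gene values are exchangeable within
  sets; spatial autocorrelation along chromosomes is not modeled.
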