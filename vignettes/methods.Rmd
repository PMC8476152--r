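---
title: "Models and methods behind straitsadmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind straitsadmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(straitsadmix)
```

straitsadmix infers the amount, sex bias and timing of admixture in a
recently admixed human population from three kinds of evidence: genome-wide
ancestry (PCA and f3 on allele frequencies, global fractions on
local-ancestry tracts), sex-linked ancestry (X-vs-autosome contrasts), and
uniparental lineages (MT and Y haplogroups). This vignette describes each
model, its assumptions, the tunable parameters, and the numerical and
design choices that were genuinely open — and what the synthetic-data tests
do and do not demonstrate about real data.

## The synthetic cohort generator

Every stage is exercised on synthetic cohorts whose defaults describe the
study conditions the package targets: two-way Chinese–Malay admixture with
a trace Indian founder component, source divergence FST = 0.012, admixture
6.55 generations (190 years at 29 years/generation) before present, and
sex-biased founder proportions — maternal Chinese/Malay/Indian
0.87/0.12/0.01, paternal 0.95/0.05/0. Components:

* **Allele frequencies** follow the Balding–Nichols model: population
  frequency `p_k ~ Beta` with mean `p` (ancestral) and variance
  `F·p(1−p)`. Two populations drawn this way have expected pairwise Hudson
  FST equal to `F`. Frequencies are clipped to `[1e-6, 1 − 1e-6]` to keep
  downstream binomial draws non-degenerate.
* **Local-ancestry tracts** follow a Markov approximation: breakpoints are
  a Poisson process at rate `g` per Morgan and segment ancestries are drawn
  independently from the proportion vector `alpha`. This is *not* a
  pedigree simulation — an F1 individual is not exactly `g = 1` under this
  model — but it is exactly the process whose indicator autocovariance is
  `alpha(1−alpha)·exp(−g d)`, making the simulator internally consistent
  with the dating estimator. Segments are half-open `[start, end)` in cM
  and tile each chromosome exactly.
* **The genetic map** defaults to 22 chromosomes proportioned like the
  human sex-averaged map and rescaled to 35 Morgans total; the total is
  configurable because tract-length normalization depends on it and no
  single canonical value exists.
* **Sex bias** enters twice: X-chromosome tracts use ancestry proportions
  `(2·maternal + paternal)/3` (two thirds of X generations are spent in
  females) while autosomes use the mid-parent mean; and founder lineages
  drive haplogroups — each sample's maternal founder ancestry is drawn from
  the maternal proportions and its MT haplogroup from that ancestry's
  table, with Y haplogroups likewise for males only.
* **Haplogroup tables** default to plausible spectra built around the
  ancestry-informative markers of the system (MT haplogroup E common in
  Malays and rare in Chinese, D the reverse; Y haplogroups O1/O2 with
  strongly different odds between Chinese and Malays). A `diagnostic =
  TRUE` variant gives each ancestry a private haplogroup, which removes all
  shrinkage from the Bayes estimator and is used for recovery tests.

One global seed drives named substreams (`sex`, `haplogroups`, `tracts`,
`tracts_x`, `frequencies`, `genotypes`), so stages can be re-run
independently and every run is bit-reproducible.

What the generator does **not** emulate: linkage disequilibrium within
ancestral populations, genotyping or phasing error, local-ancestry caller
bias (tracts are truth, optionally with synthetic posteriors), related
individuals, and continuous or multi-wave migration. Passing recovery tests
therefore demonstrates correctness of the estimators under their own model
assumptions, not robustness to the artefacts of real pipelines.

## Population structure

PCA standardizes dosages by `sqrt(2p(1−p))` with `p` from the reference
panel, drops zero-variance variants, fixes each component's sign so its
dominant loading is positive, and projects study samples by loading
multiplication (missing genotypes impute to the reference mean, i.e. the
standardized origin). This simple projection — rather than a
resampling-based Procrustes projection — is a documented simplification;
the Procrustes similarity statistic
`t0 = tr(Λ)/sqrt(tr(Xc'Xc)·tr(Yc'Yc))` is provided separately and equals 1
for identical shapes after translation, scaling and rotation.

Outlier removal recomputes per-PC means and SDs on the kept set and drops
samples beyond `n_sd = 3` SDs on any of the top `k = 3` PCs until a fixed
point; the result is deterministic, idempotent and order-independent.
Concentration ellipses use the bivariate-Gaussian Mahalanobis threshold
`qchisq(level, df = 2)` (5.99 at 95%). Kernel densities along the
centroid–centroid axis use Silverman's rule bandwidth by default.

## Ancestry fractions and group comparisons

Local-ancestry windows with posterior vectors are masked: a window keeps
its argmax ancestry only when the maximum posterior exceeds 0.9 (ties
broken by fixed column order — the choice is immaterial for continuous
posteriors but must be deterministic). Global fractions are length-weighted
in cM over both haplotypes, excluding Unknown tracts from the denominator;
a sample with zero known length is flagged `NA` rather than zeroed. Group
means carry t-based 95% CIs; comparisons use Welch's t-test, the paired
t-test on matched samples, Spearman correlation, or Fisher's exact test on
haplogroup composition tables (Monte-Carlo p with a fixed seed beyond
2×2).

## The f3 test

`f3(target; A, B)` is the SNP-mean of `(c − a)(c − b)`. When haploid target
counts are available the estimator subtracts `c(1−c)/(n_C − 1)` per SNP,
removing the upward bias from sampling the target frequency; both modes are
exposed and recorded because published pipelines differ in whether the
correction applies. Standard errors use contiguous equal-count blocks
(remainder spread over leading blocks; 727 blocks by default, matching
common practice for ~1M SNPs) and the weighted block jackknife, which
reduces to the classical delete-one jackknife for equal blocks. MAF
filtering (> 0.05) and 2 kb thinning are available as input filters.

## Coancestry decay and dating

For ancestry A, the curve value at distance `d` is
`mean[I_A(x)·I_A(x+d)] − mean[I_A]²` over all haplotypes and positions,
cross-chromosome pairs excluded. Numerically, the position average is
evaluated in closed form rather than by sampling anchor positions: per
haplotype–chromosome the lag-`d` cross-product integral equals the overlap
length between the ancestry-A tract set and its `d`-shifted copy, a
piecewise-linear function of `d` whose kinks are accumulated and evaluated
exactly at every bin center (tract pairs that lie entirely left of the
anchor tract, or start beyond the grid maximum, contribute exactly zero and
are pruned). This removes any anchor-grid/bin-width interaction on the fine
grid and keeps the computation fast enough for bootstrap and multi-seed
recovery suites. Grids follow the two standard choices: 1–50 cM at 0.1 cM
for recent events, and 1–10 cM at 0.01 cM for ancient events, whose decay
is essentially complete within 10 cM.

Fitting minimizes weighted least squares (weights = per-bin position
measure) of `a + b·e^{−λd}` or `a + b1·e^{−λ1 d} + b2·e^{−λ2 d}`, `d` in
Morgans. Rates are profiled: for each candidate λ the intercept and
amplitudes are solved linearly, and λ is optimized on a log grid spanning
0.2–2000 followed by local refinement (tolerance 1e-10), making the fit
deterministic with no starting-value sensitivity. The two-date model uses
Nelder–Mead over `(log λ1, log λ2)` from six starts with an
identifiability guard `λ2/λ1 > 2`; rates are reported ordered. A fit is
flagged `no_signal` when the amplitude is non-positive or smaller than
three times the residual SD — a flat curve cannot be dated. Dates are
`λ × 29` years by default (configurable). Bootstrap CIs resample
individuals with replacement, re-aggregating the stored per-sample curve
components rather than recomputing tract overlaps.

The null test deserves a note. Permuting ancestry labels across *segments*
does not remove the decay signal: segment persistence itself carries
`exp(−g d)`, so such a null reproduces the observed curve almost exactly.
The package instead re-tiles each haplotype into windows the size of the
grid minimum (1 cM by default) and permutes window labels within the
haplotype, which preserves the marginal ancestry fraction but destroys
continuity at all measured distances. Observed data and null replicates are
scored identically by the total fitted amplitude; the empirical p-value is
the fraction of null amplitudes reaching the observed one. On cohorts with
iid window labels the p-value is approximately uniform; on admixed cohorts
it falls below `1/B`. This window null is a stated substitute for the
chunk-permutation nulls of haplotype-painting pipelines, not a claim of
equivalence.

## The uniparental Bayes estimator

Reference haplogroup frequencies `P(H|A)` (optionally with a Laplace
pseudocount) combine with a prior `P(A)` — the autosomal ancestry fractions
restricted to the ancestries present in the haplogroup reference and
renormalized — to give `P(A|H)` per haplogroup. The contribution of
ancestry A is the mean posterior over samples; haplogroups absent from
every reference population are flagged undefined and their carriers
excluded (and counted) rather than silently zeroed. Inference resamples
each sample's founder ancestry from its posterior for `R = 1000`
realizations: CIs are 2.5/97.5 percentiles of realization-level
proportions, and the p-value for "ancestry A contributed nothing" is the
fraction of realizations in which A was never drawn, reported as `<1/R`
when zero.

Two properties frame interpretation. With fully diagnostic haplogroups the
estimator returns the realized founder-lineage fraction exactly,
independent of the prior. With weakly informative tables it shrinks toward
the prior — the estimate interpolates monotonically between evidence and
prior as tables flatten — so the resampling CI quantifies categorical
sampling noise around the estimator's own expectation, not distance to the
true founder fraction. The female:male founder ratio per ancestry is the
ratio of maternal (MT) to paternal (Y) contributions, under the assumption
of equal founder sex counts.

## Problem sizes and test design

The recovery suites run at sizes chosen to make Monte-Carlo error small
relative to the tolerances while keeping the full test run in minutes: 200
diploid genomes on a 35-Morgan map across 20 seeds for date recovery
(median within ±15% at both 190 and 1,612 years), 50,000 SNPs and 200
diploids per population for the FST calibration (±0.002), and cohorts of
115 (MT) and 40 (Y) samples across 20 seeds for founder-contribution
recovery. Property tests (tract tiling, Poisson breakpoints, posterior
normalization, jackknife-vs-brute-force, Procrustes invariance, outlier
idempotence, null-test calibration) use smaller fixtures with fixed seeds.

## Known limitations

* The tract model ignores pedigree structure and drift in segment
  ancestry; dating accuracy degrades for events younger than a few
  generations, where the Poisson approximation is coarsest.
* The coancestry curve uses hard tract labels; posterior-weighted curves
  are not implemented, so heavy masking can bias the amplitude (though not
  the rate) of the decay.
* The X/autosome contrast of founder proportions is weakly identified at
  cohort sizes near 100 when maternal and paternal contributions differ by
  only a few points; the package reports the direction and the paired test
  but recovery of the difference needs larger cohorts.
* The two-date model's identifiability guard (`λ2/λ1 > 2`) means two pulses
  closer than a factor of two in age are reported as one.
* No multiway source decomposition: curves are per-ancestry-indicator, and
  the composition of each admixing source is out of scope.
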