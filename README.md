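# straitsadmix

Tools for reconstructing the admixture history of recently admixed human
populations — the motivating case being the Peranakan Chinese of the Malay
Archipelago, descendants of Chinese traders who settled among Malays several
centuries ago. Given phased genotypes, RFMix-style local-ancestry tracts and
uniparental (MT/Y) haplogroup calls, the package answers three questions:

1. **How much admixture?** Length-weighted global ancestry fractions from
   local-ancestry tracts (with posterior masking), and the three-population
   test `f3(target; A, B) = mean over SNPs of (c − a)(c − b)` with
   block-jackknife standard errors — a significantly negative `f3` indicates
   the target is admixed between populations related to the two sources.
2. **Was it sex-biased?** X-vs-autosome ancestry comparisons, and a Bayes
   estimator of maternal/paternal founder contributions from haplogroups:
   with reference haplogroup frequencies `P(H|A)` and an autosomal prior
   `P(A)`, each observed haplogroup yields `P(A|H) ∝ P(H|A)·P(A)`, the
   contribution of ancestry A is `ρ_A = mean_i P(A|H_i)`, and confidence
   intervals and p-values come from categorical resampling of founder
   ancestries (1,000 realizations by default).
3. **When did it happen?** The ancestry-indicator autocovariance
   `cov(I_A(x), I_A(x + d))` decays as `α(1 − α)·e^{−g d}` with genetic
   distance `d` (Morgans) when admixture happened `g` generations ago;
   fitting `a + b·e^{−λ d}` (or a two-exponential model for two pulses) and
   multiplying `λ` by a generation time of 29 years dates the event, with
   bootstrap CIs and a window-permutation null test.

Because the real study cohorts of this kind are access-restricted, the
package includes a first-class synthetic-cohort generator that reproduces
the statistical structure the methods assume: Balding–Nichols reference
allele frequencies at a chosen FST, Poisson-process ancestry tracts (rate
`g` per Morgan), sex-biased founder lineages with ancestry-specific MT/Y
haplogroup tables, and X-chromosome tracts mixed with maternal/paternal
weights 2/3 and 1/3. Every analysis stage is therefore testable end-to-end
without any data download.

## Worked example

Simulate a 115-sample cohort admixed 6.55 generations ago with sex-biased
founder proportions (maternal Chinese/Malay/Indian 0.87/0.12/0.01, paternal
0.95/0.05/0), then quantify, test and date the admixture:

```r
library(straitsadmix)

cfg <- sim_config(n_samples = 115L, g = 6.55, seed = 7L)
cohort <- simulate_cohort(cfg)

## 1. how much? tract-based global ancestry fractions
fa <- global_fractions(cohort$tracts, "autosomes")
fx <- global_fractions(cohort$tracts, "X")
sprintf("Malay ancestry: autosomes %.2f%%, X %.2f%%",
        100 * mean(fa$frac_Malay), 100 * mean(fx$frac_Malay, na.rm = TRUE))
#> "Malay ancestry: autosomes 8.69%, X 10.75%"
compare_groups(fx$frac_Malay, fa$frac_Malay, mode = "paired_welch")$p_value
#> 0.0313   # X carries more Malay ancestry: female-biased contribution

## 2. who contributed? Bayes haplogroup estimator (maternal line)
prior <- c(Chinese = 0.933, Malay = 0.0562, Indian = 0.0092)
mt <- cohort$haplogroups[cohort$haplogroups$system == "MT"]
estimate_uniparental(mt$haplogroup, cfg$haplogroup_freqs$MT,
                     prior / sum(prior), R = 1000, seed = 7)
#> Ancestry contributions (n = 115 used, 0 excluded, R = 1000)
#>   Chinese  rho =  93.1%  95% CI [ 88.7,  97.4]  P <0.001
#>   Malay    rho =   6.1%  95% CI [  1.7,  10.4]  P <0.001
#>   Indian   rho =   0.9%  95% CI [  0.0,   2.6]  P 0.375

## 3. when? coancestry-decay dating
cv <- coancestry_curve(cohort$tracts, "Malay", grid = c(1, 50, 0.1))
fit_decay(cv, "one_date")
#> Exponential decay fit (one_date, 29 years/generation)
#>   lambda1 = 6.630 generations -> 192 years (amplitude 0.0803)
#>   intercept -0.000365, weighted SSE 8.123e-06
```

The simulated truth is 6.55 generations (190 years); the decay fit recovers
192 years. The maternal Malay contribution estimate (6.1% here) is shrunk
toward the autosomal prior because the default haplogroup tables are only
moderately ancestry-informative — with fully diagnostic haplogroups the
estimator recovers the founder fraction exactly (see the vignette).

`run_pipeline(pipeline_config(seed = 1), "out/")` executes all six stages
(simulate → pca → fractions → f3 → uniparental → date) and writes TSV/JSON
outputs plus a manifest; reruns with the same seed are byte-identical.

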