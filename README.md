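# lemmafrag

Bayesian analysis of barley husk fragmentation from controlled impact
assays.

## The problem

Grain skinning — damage to or loss of the husk during mechanical handling —
is a costly quality defect in malting barley. The lemma, the larger of the
two husk organs, is the one most often lost. A simple way to compare the
mechanical resilience of lemmas across varieties and developmental stages
is an impact assay: a detached lemma is oscillated with a ceramic ball at
50 Hz for 10 s, the debris is photographed, the image is thresholded to a
binary mask, and particle analysis (minimum fragment size 500 pixels)
yields the number of fragments and the area of each one. Varieties whose
lemmas shatter into many small fragments are less resistant to impact and
carry a higher skinning risk.

This package implements the statistical pipeline behind that readout, for
anyone running or reanalysing such assays.

## The models

**Fragment number.** The count of fragments per lemma (an intact lemma is
recorded as 1) is modelled as

    y_i ~ Poisson(lambda),      lambda ~ Gamma(0.001, 0.001)

per group (variety x growth stage). The posterior is conjugate,
Gamma(0.001 + sum y, 0.001 + n), and is summarised by its mean and 95%
highest-density interval (HDI). `fit_counts()` samples it with a Gibbs
sampler (3 chains x 50,000 retained draws after 10,000 adaptation/burn-in
iterations by default); `lambda_posterior()` gives the closed form.

**Fragment area.** Individual fragment areas (pixels) are modelled as

    y_i ~ Gamma(alpha, beta),   alpha, beta ~ Gamma(0.001, 0.001)

(shape-rate parameterization), fitted by Metropolis-within-Gibbs random
walk on (log alpha, log beta) with burn-in-adapted proposal scales
(`fit_areas()`, 3 chains x 100,000 retained draws by default). The
quantity of interest is the mean fragment area `mu = alpha / beta`,
derived draw-by-draw. A Weibull likelihood (`distribution = "weibull"`)
and a two-component parent/child Gamma mixture (`fit_area_mixture()`) are
available as alternatives.

**Comparison.** Groups are compared by the elementwise difference of their
posterior draws (`compare_lambda()`, `compare_mu()`): mean difference, its
HDI, and the posterior probability of the difference's sign. Convergence
is monitored with the Gelman-Rubin shrink factor (< 1.1 criterion),
effective sample size, Monte Carlo standard error and lag-1
autocorrelation; model adequacy with posterior predictive checks
(`ppc()`).

Around the models sit a seeded synthetic assay generator
(`generate_study()`, including an area-conserving sequential breakage
mode), binary-mask particle measurement (`measure_fragments()`,
`measure_batch()`), a frequentist stage for structural traits
(`anova_two_way()`, `tukey_hsd_cells()`, `compact_letters()`,
`ratio_of_means_ci()`), and a configuration-driven `run_pipeline()`.

## Worked example

```r
library(lemmafrag)

study <- generate_study(study_config(seed = 42))
poker <- subset(study$counts, variety == "Poker" & growth_stage == "GS65")
fit <- fit_counts(poker$fragment_count, "Poker:GS65")
fit
#> Poisson fragment-count fit: Poker:GS65 (n = 10, total = 84)
#>   lambda: mean 8.400, 95% HDI (6.617, 10.198)
#>   PSRF 1.0000 | ESS 150000 | MCSE 2.37e-03
```

Ten simulated lemmas of the high-risk variety yielded 84 fragments; the
posterior mean rate is 8.4 fragments per lemma with a 95% HDI of
(6.6, 10.2), and the chains are fully converged. Comparing against the
low-risk variety:

```r
gp <- subset(study$counts, variety == "GoldenPromise" & growth_stage == "GS65")
fit_gp <- fit_counts(gp$fragment_count, "GoldenPromise:GS65",
                     config = sampler_config(seed = 2))
compare_lambda(fit_gp, fit)
#> Posterior difference in lambda: GoldenPromise:GS65 - Poker:GS65
#>   mean -6.5, 95% HDI (-8.497, -4.523)
#>   P(diff < 0) = 1.000, P(diff > 0) = 0.000
#>   HDI excludes 0
```

The low-minus-high difference is wholly below zero: the low-risk variety
forms significantly fewer fragments. Area fits report `mu` on the
10^6-pixel scale and flag poorly mixed small-sample fits:

```r
a <- subset(study$areas, variety == "Henni" & growth_stage == "GS77")
fit_areas(a$fragment_area_px, "Henni:GS77",
          config = sampler_config(n_iter = 20000, seed = 3))
#> Gamma fragment-area fit: Henni:GS77 (n = 12 fragments)
#>   alpha  mean 3.53, 95% HDI (1.046, 6.309)
#>   beta   mean 6.266e-07, 95% HDI (1.712e-07, 1.156e-06)
#>   mu     mean 5.791, 95% HDI (3.972, 7.781) x 10^6 px
#>   acceptance 0.34 | max PSRF 1.002 | min ESS 819
#>   note: high lag-1 autocorrelation; interpret HDIs with care
```

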