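# resilnorm

Two-stage genetic analysis of **resilience to unrecorded environmental
challenges** from high-frequency phenotype records, with daily feed
intake (DFI) of growing lambs on automatic concentrate feeders as the
motivating application.

Challenge events on a farm — heat, disease pressure, management
interventions, feeder failures — are rarely recorded, but they leave a
fingerprint: on a bad day, animals react differently from one another
and the *cross-animal* variation of the phenotype inflates.
`resilnorm` turns that fingerprint into a quantitative genetic
analysis:

1. **Challenge detection.** For each test day, compute the cross-animal
   coefficient of variation of DFI and analyse its natural log.  Fit a
   two-component Gaussian mixture to the day-level log(CV) values by
   EM (component count confirmed by parametric bootstrap).  The
   posterior probability that day *j* belongs to the high-CV component,
   *p<sub>j</sub>* ∈ [0, 1], is a continuous environmental descriptor:
   the probability that an unrecorded challenge occurred that day.

2. **Reaction-norm animal model (RNAM).** Using *p<sub>j</sub>* as the
   environmental gradient,

   *y<sub>ijk</sub>* = yearACF*<sub>i</sub>* + *b*₁ day*<sub>j</sub>* +
   *a*₀*<sub>k</sub>* + *a*₁*<sub>k</sub>* *p<sub>j</sub>* +
   *pe*₀*<sub>k</sub>* + *pe*₁*<sub>k</sub>* *p<sub>j</sub>* +
   *e<sub>ijk</sub>*,

   where (*a*₀, *a*₁) ~ N(0, **G**₀ ⊗ **A**) are breeding values for
   level (performance at *p* = 0) and environmental sensitivity (an
   animal with *a*₁ ≈ 0 is resilient), (*pe*₀, *pe*₁) ~ N(0, **P**₀ ⊗
   **I**) are permanent-environmental effects, and **A** is the
   pedigree numerator relationship matrix.  Variance components are
   estimated by EM/average-information REML or by Gibbs sampling.

From a fit the package derives the genetic-variance and heritability
trajectories *h*²(*p*), the correlation Cor(*a*₀, *a<sub>p</sub>*)
between breeding values across the gradient (its decay below 1
quantifies G×E interaction), the boundary-corrected likelihood-ratio
test of the reaction-norm terms (½χ²₂ + ½χ²₄ mixture, evaluated in log
space), and a three-group resilience classification of animals by
slope in genetic SD units.

A first-class simulator (`sim_config()`, `simulate_dataset()`)
generates pedigrees, challenge-day processes, phenotypes and feeder
visits under the same model, with exported ground truth, so every
stage is testable without access to proprietary data.

## Worked example

```r
library(resilnorm)

## 1. Simulate a dataset at reduced scale (4 cohorts x 75 lambs, 40 days)
cfg <- sim_config_small(n_animals = 300, n_days = 40, n_years = 4, seed = 101)
sim <- simulate_dataset(cfg)

## 2. Day-level variability and challenge probabilities
dv  <- compute_day_variability(sim$records, min_animals = 10)
mix <- fit_mixture(dv$log_cv, k = 2, init_seed = 1)
mix
#> Gaussian mixture, 2 component(s), logLik 36.161485
#>     weight       mean        sd
#> 1 0.875879 -1.5618969 0.1335445
#> 2 0.124121 -0.9871897 0.1777952
dv <- challenge_probabilities(mix, dv)
mean(dv$p)
#> [1] 0.1241174
```

The bulk of days sits near log(CV) ≈ −1.56 (CV ≈ 21 %); a minority
component of high-variance days — the putative challenge days — lies
well above it, and each day receives a posterior challenge probability.

```r
## 3. Reaction-norm animal model by REML
rec  <- merge(sim$records, dv[, c("year", "test_day", "p")],
              by = c("year", "test_day"))
ainv <- a_inverse(sim$ped)
fit  <- reml_fit(rnam_spec(residual = 0.5), rec, ainv,
                 em_iters = 15, max_ai_iters = 60)
fit
#> Reaction-norm animal model (RNAM) - converged in 28 iterations
#> G0 (genetic):
#>             [,1]        [,2]
#> [1,]  0.01432147 -0.01637543
#> [2,] -0.01637543  0.02427432
#> P0 (permanent environment):
#>             pe0         pe1
#> pe0  0.03506735 -0.03270083
#> pe1 -0.03270083  0.14450133
#> residual: 0.117327 / 0.478599
#> -2 logL: 11424.94536
```

The fitted components sit on the scale of the generating values
(level genetic variance 0.016 kg², normal-day residual 0.120 kg²); the
negative level–slope covariance means animals with high intake
potential tend to reduce intake more under challenge.

```r
## 4. Trajectories and resilience groups
summarize_reaction_norm(fit$vc, grid = c(0, 0.3, 1))
#>     p var_genetic     var_pe          h2  cor_a0_ap
#> 1 0.0 0.014321472 0.03506735 0.085903361  1.0000000
#> 2 0.3 0.006680903 0.02845197 0.043820654  0.9618887
#> 3 1.0 0.005844934 0.11416701 0.009764159 -0.2244957
table(classify_resilience(fit)$group)
#> decreasing     stable increasing
#>         43        353        44
```

Heritability and the cross-environment genetic correlation change
along the gradient — the signature of genotype-by-environment
interaction — and most animals fall in the stable (resilient) group,
within ±1 genetic SD of zero slope change.

A command-line pipeline wrapping the same functions is installed at
`inst/cli/resilnorm` (subcommands `simulate`, `daystats`, `mixture`,
`fit`, `summarize`).

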