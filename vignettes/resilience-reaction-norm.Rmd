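---
title: "Detecting unrecorded environmental challenges and estimating the genetics of resilience"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting unrecorded environmental challenges and estimating the genetics of resilience}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resilient animals keep performing when rearing conditions deteriorate.
Selecting for resilience requires knowing *when* conditions
deteriorated, but on most farms environmental challenges — heat
episodes, disease pressure, management interventions, feeder
breakdowns — are neither controlled nor recorded.  What is increasingly
recorded, through automatic feeders, milking robots and weighing
platforms, is the phenotype itself at high frequency: here, the daily
feed intake (DFI, kg) of growing lambs on automatic concentrate
feeders.

`resilnorm` implements a two-stage analysis of such data:

1. **Challenge detection.**  A day on which something went wrong shows
   inflated variation *across* animals.  For every test day we compute
   the cross-animal coefficient of variation of DFI and fit a
   two-component Gaussian mixture to the day-level `log(CV)` values by
   EM.  The posterior probability that a day belongs to the challenge
   component, `p_j in [0, 1]`, is a continuous, data-driven
   environmental descriptor — no climate records, no reference growth
   curve, no arbitrary cut-off.
2. **Genetic analysis of sensitivity.**  The `p_j` enter a linear
   reaction-norm animal model (RNAM) as the environmental gradient:

   `y_ijk = yearACF_i + b1 day_j + a0_k + a1_k p_j + pe0_k + pe1_k p_j + e_ijk`

   with `(a0, a1) ~ N(0, G0 (x) A)` (A the pedigree numerator
   relationship matrix) and `(pe0, pe1) ~ N(0, P0 (x) I)`.  `a0_k` is
   the breeding value under non-challenging conditions (`p = 0`) and
   `a1_k` the breeding value for environmental sensitivity: an animal
   with `a1` near zero is resilient.

## Why the CV and not the variance

DFI grows as lambs grow, so the cross-animal variance carries a scale
effect that would masquerade as day-to-day heterogeneity.  The CV
(cross-animal SD divided by the mean) removes the first-order scale
effect; the natural log symmetrizes it.  Days are retained only with at
least `min_animals = 10` records (smaller days give unstable CVs) and
days with zero variance are excluded rather than stored as `-Inf`.
The SD uses the sample (n − 1) denominator; with cohorts of around 120
animals the choice is numerically negligible, but it is fixed for
reproducibility.

## Stage one: the mixture machinery

`fit_mixture()` maximizes the k-component heteroscedastic normal
mixture likelihood by EM.  Numerical choices:

* **Initialization.**  A deterministic quantile split (the top 15 % of
  values seed the high component) plus `n_restarts = 5` random
  responsibility draws; the best log-likelihood wins.  EM likelihood is
  checked to be non-decreasing at every iteration.
* **Convergence.**  Relative log-likelihood change below `1e-8`,
  at most 1000 iterations.
* **Degeneracy.**  Gaussian mixture likelihoods are unbounded as a
  component variance goes to zero; a variance floor of
  `1e-6 x sd(data)` rejects such runs, and a run where all restarts
  degenerate errors out rather than returning a spike.
* **Label order.**  Components are stored sorted by increasing SD so
  that serialized fits are reproducible regardless of initialization.

**Which component is "the challenge"?**  In the motivating analyses
the challenge component has both the larger mean and the larger SD, so
the question does not arise.  In small simulated datasets with ~10
challenge days, however, the minority component is frequently fitted
with a *smaller* SD than the bulk, and a largest-SD rule silently
inverts every probability.  Because the challenge component is, by its
scientific meaning, the one that captures the *high-CV days*,
`posterior_probabilities()` identifies it by the largest mean (a
`"largest_sd"` option is provided for comparison).

The number of components is not assumed: `bootstrap_component_test()`
simulates data from the fitted k-component model, refits both k and
k + 1, and compares the observed likelihood-ratio statistic with its
bootstrap distribution (p-value with the +1 correction;
`n_boot = 100` by default).  `select_num_components()` applies the
test sequentially from k = 1.

## Stage two: pedigree and mixed-model machinery

* `a_inverse()` assembles the sparse inverse numerator relationship
  matrix directly from the pedigree by Henderson's rules, with
  Mendelian-sampling variances adjusted for parental inbreeding
  (Meuwissen–Luo algorithm).  Ignoring inbreeding is detectably wrong
  on deep pedigrees; a flag reproduces the classical rules for
  comparison.  The dense tabular-method matrix (`make_A()`) serves as
  the test oracle, never as the computational route.
* `reml_fit()` estimates `G0`, `P0` and the residual(s) by restricted
  maximum likelihood: 50 EM iterations by default (monotone, robust to
  poor starts), then average-information Newton updates until the
  relative parameter change falls below `1e-8`.  An AI step is accepted
  only if it does not worsen the restricted likelihood; otherwise it is
  step-halved and, failing that, replaced by an EM step.  Updates that
  leave the positive-semi-definite cone by rounding are bent back by
  lifting eigenvalues to `1e-8 x trace`.  Starting values: residual at
  half the phenotypic variance, intercept variances at a quarter of it,
  slope variances at 0.01 kg², zero covariances.
* The environmental covariate enters **raw** (not centred), so `a0` is
  the breeding value at `p = 0` exactly; the day-on-test covariate is
  centred internally for conditioning and reported on the raw scale.
* `gibbs_fit()` provides the Bayesian counterpart: all location
  effects are drawn as one block from their joint normal full
  conditional through the sparse Cholesky factor, `G0` and `P0` from
  inverse-Wishart full conditionals (weakly informative prior: scale
  `1e-4 I`, k + 1 degrees of freedom), residuals from scaled
  inverse-chi-square conditionals with a flat (nu = −2) prior.
  Posterior means and REML estimates are distinct estimators that
  coincide only to O(1/n); the package's cross-validation test
  therefore requires agreement within `max(3 x batch-means MCSE, 1 %)`.
* The residual is homogeneous by default; `residual = t` splits
  records at `p_j > t` into a "high" class with its own variance, which
  is also the model matching the simulator's challenge-day residual
  inflation.

## Derived summaries

With fitted components, the package evaluates along `p in [0, 1]`:
genetic variance `s2_a0 + 2 p s_a0a1 + p^2 s2_a1` (and the analogue for
permanent environment), heritability `h2(p)`, and the correlation
`Cor(a0, a_p)` between breeding values at `p = 0` and at `p`, whose
decay below 1 quantifies genotype-by-environment interaction.  The
reaction-norm terms are tested against the reduced animal model by a
likelihood-ratio test whose null distribution is the equal-weight
mixture of chi-square distributions with 2 and 4 degrees of freedom
(two variances on the boundary plus two covariances); survival
functions are combined in log space so p-values far beyond underflow
(1e-114 and smaller) remain exact.  `classify_resilience()` standardizes
`a1` by the level genetic SD (`sqrt(s2_a0)`; the total additive SD at
`p = 1` is available as an option, since either convention is
defensible) and splits animals at ±1 SD into decreasing / stable /
increasing groups.

## The simulator and what it does (not) show

`sim_config()` defaults encode the study conditions the package is
validated under: 8 yearly cohorts totalling 951 phenotyped animals,
438 (year, day) cells, a pedigree of ~5,100 animals, true components
`G0 = [[0.016, -0.011], [-0.011, 0.038]]`,
`P0 = [[0.034, -0.031], [-0.031, 0.104]]`, residual 0.120 kg², and a
challenge probability of 0.09 per day.  Challenge days act through two
channels: they switch on the slope effects (`s_j = 1` in the generative
model) and they multiply the residual SD by 2 — slope variance alone,
at these magnitudes, produces only weak day-level bimodality.  A
lognormal day-level jitter of the residual SD (sd 0.08 on normal days,
0.22 on challenge days) together with the growth trend spreads the
day-level log CV within each class to roughly 0.13 / 0.26, the spread
observed in real feed-intake data; with the 2x inflation the simulated
challenge component sits higher above the bulk (about 0.6 log units)
than real challenge days typically do, a deliberate trade of realism
for unambiguous ground truth.  Baseline intake 1.7 kg with a
0.012 kg/day growth slope puts the normal-day log CV near −1.6.

The generator draws breeding values over the whole pedigree by the
Mendelian-sampling recursion (so their covariance is exactly
`G0 (x) A`, inbreeding included), and can split daily intakes into
Poisson(14.56)-distributed feeder visits by a symmetric Dirichlet for
visit-level testing.  All randomness flows from one seed; identical
configurations give byte-identical outputs.

What passing the simulation-based tests does **not** show: the
generator's challenges are i.i.d. Bernoulli days with a purely
multiplicative residual effect; real challenges cluster in time, differ
in intensity, and can shift the mean as well as the variance.  The
true covariate is binary while the analysis regresses on the estimated
continuous `p_j`, which mirrors the two-stage error structure of a real
analysis (estimates are mildly attenuated when day classification is
imperfect), but it cannot reveal biases that a structurally different
environment would induce.

## Validation strategy and problem sizes

The test suite validates each layer against an independent oracle:
brute-force group-and-sum for visit aggregation; the tabular-method
relationship matrix (dense inversion) for the sparse A-inverse on all
pedigrees up to 200 animals; dense GLS for the sparse mixed-model
equations; the closed-form ANOVA solution of the balanced
repeatability model for REML; the reference EM of the `mclust` package
(to 1e-6, from identical starting values at machine-level tolerance)
for the mixture stage; and direct formula evaluation for every derived
summary.  Parameter recovery runs the full two-stage pipeline on 20
simulated replicates of 4 cohorts x 75 animals x 40 days — chosen so
that stage one sees 160 day cells, enough for a stable mixture fit —
and requires every component to lie within three empirical SEs of the
generating values; the Gibbs sampler is cross-validated against REML
on a single well-identified dataset (200 unrelated animals with
repeated records, no permanent environment, since with a shallow
pedigree the genetic and permanent-environmental intercepts are nearly
confounded and their posterior mixes slowly).  These sizes keep the
whole suite within a few minutes on one core while leaving every check
sharp.

## Known limitations

* Linear reaction norms only; quadratic or change-point norms are not
  implemented.
* One phenotype at a time (no multi-trait or maternal-effect models);
  no genomic relationships or unknown-parent groups.
* REML computes selected inverse elements through a dense inverse of
  the sparse Cholesky factor, which is comfortable up to a few
  thousand equations but not designed for national-evaluation scale.
* The day-level CV requires groups of comparable animals recorded
  simultaneously; sporadically recorded or heterogeneous groups give a
  mixture with a single detectable component.
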