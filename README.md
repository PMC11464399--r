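# lifecourse

Bayesian relevant life-course exposure modelling for longitudinal cohorts.

## The problem

When in life does an exposure matter? For a risk factor measured repeatedly
from childhood to young adulthood — here non-HDL cholesterol (total minus
HDL cholesterol, mmol/l) — and a mid-adulthood outcome such as carotid
plaque, life-course epidemiology distinguishes an **accumulation** model
(every life stage contributes equally), **critical-period** models (only
one stage matters) and a **sensitive-period** model (all stages contribute,
unequally). This package is for epidemiologists and biostatisticians who
want to fit that question directly rather than compare ad-hoc per-window
regressions.

## The model

For participant *i* with life-stage exposures
*X*<sub>i1</sub> (childhood: mean z-score over ages 6, 9, 12),
*X*<sub>i2</sub> (adolescence: 15, 18) and
*X*<sub>i3</sub> (young adulthood: 21, 24):

    eta_i = alpha + beta * (w1*X_i1 + w2*X_i2 + w3*X_i3) + gamma' C_i

with **w** on the 3-simplex (Dirichlet(1,1,1) prior) and the lifetime
effect *beta* given a Cauchy(0, 2.5) prior. Plaque presence (0/1) is
modelled with a Poisson likelihood and log link, so exp(beta) is the
lifetime **relative risk** per 1 s.d. of exposure; log plaque area among
the plaque-positive is Gaussian, so beta is an additive effect. The
stage-specific effect is beta·w<sub>k</sub> per posterior draw
(exp(beta·w<sub>k</sub>) as a stage RR), and the stage RRs multiply exactly
to the lifetime RR. The fitted weight vector is classified against the
life-course hypotheses by Euclidean distance to the archetypes (1/3,1/3,1/3),
(1,0,0), (0,1,0), (0,0,1).

Around the model the package provides: validated cohort readers/writers
(long-format CSV), individual growth-curve interpolation of missed waves
(cubic-age linear mixed model via lme4), age- and sex-specific z-scoring,
life-stage averaging, trapezoidal AUC covariate summaries, multiple
imputation of covariates by predictive mean matching with pooling of
posterior draws across imputations, ternary-plot coordinates, and a
synthetic-cohort generator that emulates a prospective cardiovascular
cohort design (n ≈ 2,000, waves at ages 3–24, ≈39.6% plaque prevalence,
lipid tracking correlations ≈0.6–0.8) so the whole pipeline runs and is
tested without restricted cohort data. Posterior sampling uses the
package's adaptive Metropolis sampler (Rcpp); it is cross-checked in the
test suite against closed-form oracles and an independent rjags fit.

## Worked example

```r
library(lifecourse)

cfg <- pipeline_config(list(
  simulate = list(n = 1000, seed = 42, outcome_seed = 43, missing_seed = 44),
  model    = list(outcomes = "plaque_presence", adjustment = "model1",
                  exposure_scale = "zscore", stratify_by_sex = FALSE,
                  birth_year_categorical = FALSE),
  brlm     = list(chains = 4, warmup = 2000, draws = 1000, thin = 20, seed = 45)
))
report <- run_pipeline(cfg)
print(report)
```

This simulates a 1,000-participant cohort under a true lifetime RR of 1.22
with equal stage weights, fills its missed waves with the growth-curve
model, standardizes, fits the life-course model adjusted for sex and year
of birth, and prints:

```
|  | Carotid plaque (RR), model1 |
|---|---|
| Lifetime effect | 1.23 (1.10-1.37) | - |
| Childhood, 6 to 12 years | 1.09 (1.00-1.23) | 41.7 (2.3-86.4) |
| Adolescence, 15 to 18 years | 1.06 (1.00-1.18) | 26.6 (1.0-74.6) |
| Young adulthood, 21 to 24 years | 1.07 (1.00-1.19) | 31.7 (1.5-79.1) |
| Life-course model | accumulation |
| n | 1000 |
```

Reading it: the lifetime RR per 1 s.d. of non-HDL-C is estimated at 1.23
(95% credible interval 1.10–1.37, covering the generating 1.22). The
posterior-mean weights put roughly a third of the effect in each stage and
the weight vector classifies as accumulation — the generating truth —
while the wide weight intervals show how much data a three-way temporal
decomposition of a modest relative risk actually needs. The stage RRs
multiply back to the lifetime RR (1.09 × 1.06 × 1.07 ≈ 1.23) by
construction.

Individual pieces are exported too: `simulate_trajectories()`,
`fit_igc()` / `interpolate_missing()`, `zscore_by_age_sex()` /
`aggregate_life_stages()`, `fit_brlm()` with
`summarize_lifetime_effect()` / `summarize_weights()` /
`life_stage_effects()`, `classify_lifecourse()`, `impute_pmm()` /
`pool_draws()`. A thin command-line wrapper lives at `inst/cli/brlm.R`
(`simulate`, `run`, `report` subcommands). The methods vignette
(`vignettes/lifecourse-methods.Rmd`) documents the model, priors, sampler,
generator assumptions and design decisions.

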