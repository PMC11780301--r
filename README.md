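# digigap

Does the digital divide widen or narrow health inequality among older
adults? `digigap` implements the full analysis pipeline for that question
at the individual level: it scores standard health instruments, turns them
into a per-person **Kakwani relative deprivation index** of health, and
relates that index to **digital access** (broadband / smart devices /
digital devices) and **digital use** (messaging, social posting, mobile
payment) with covariate-adjusted standardized regressions, moderation and
subgroup analyses, and a propensity-score-matching sensitivity analysis.
It is aimed at epidemiologists and health economists working with ageing
cohort surveys (CHARLS-style person-level tables).

Because such microdata are restricted-access, the package ships a
synthetic cohort generator with known ground truth — calibrated marginal
prevalences for two survey waves, tunable confounding, and a tunable
treatment effect — so every stage of the pipeline is testable end to end.

## The core index

For a sample of `n` persons with health levels `y` oriented so that larger
= healthier, person *i*'s relative deprivation is

```
RD_i = (1 / (n * mu_Y)) * sum_j max(y_j - y_i, 0)
     = gamma_i * (mu_i_plus - y_i) / mu_Y
```

where `gamma_i` is the share of the sample strictly healthier than *i*,
`mu_i_plus` the mean health of that subset, and `mu_Y` the sample mean.
The index is dimensionless (invariant to rescaling `y`), zero at the
sample maximum, decreasing in own health, and its sample mean equals the
Gini coefficient of `y` — an identity the test suite verifies to 1e-10.
`RD_i` is the inequality outcome regressed on the digital-divide exposure
plus demographic, socioeconomic, health-system and regional controls, with
fully standardized coefficients and classical standard errors.

## Worked example

```r
library(digigap)

cfg <- synth_config(n = 2000, seed = 3, wave = "2018",
                    confounding_strength = 1, treatment_effect_tau = 0.4)
coh <- generate_cohort(cfg)

dat <- prepare_analysis(coh, "cognition", "access")
summary(attr(dat, "kakwani"))
#> Kakwani relative deprivation index (cognition)
#>   n = 2000
#>   mean health (mu_Y) = 23.5370
#>   Gini = mean(RD) = 0.1221

fit_cohort(coh, "cognition", "access")
#> Standardized linear model (exposure: access)
#>   n = 2000  R-squared = 0.09102
#>
#>    term      beta      se         p
#>  access -0.0827200 0.02406 5.986e-04
#>     ...
```

The cohort was generated with a health-raising digital effect
(`treatment_effect_tau = 0.4` latent SD) under confounding, and the model
recovers a negative standardized association: digitally connected persons
carry about 0.08 SD less cognitive-health deprivation, conditional on the
controls. The matched sensitivity analysis agrees in sign:

```r
rd_psm(coh, "cognition", "access", caliper = 0.02)
#> Propensity-score-matched ATT on the deprivation index
#>   dimension: cognition   exposure: access
#>   n = 2000 (1030 treated, 970 control), 613 pairs, 417 treated dropped
#>   treated mean 0.1038  control mean 0.1287
#>   ATT = -0.0249 (SE 0.0069, p = 0.0003557)
```

`run_pipeline()` executes all stages (generation or CSV ingestion,
exclusions, scoring, divide indicators, deprivation, univariate screening,
models, subgroups, PSM) and writes reproducible CSV/JSON artifacts plus a
manifest; reruns with the same configuration and seed are byte-identical.

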