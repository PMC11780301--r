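---
title: "Measuring health inequality across the digital divide: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring health inequality across the digital divide}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(digigap)
```

## The question and the outcome

Health inequality among older adults is usually summarised at the
population level (a Gini, a concentration index). This package instead
works with an *individual-level* inequality outcome: how deprived each
person is relative to everyone healthier in their sample. That makes
inequality regressable — one can ask whether persons on the favourable
side of the digital divide carry less health deprivation, conditional on
demographics and socioeconomic position.

### The Kakwani relative deprivation index

For health levels $y_1,\dots,y_n$ oriented so larger = healthier,

$$RD_i \;=\; \frac{1}{n\,\mu_Y}\sum_{j=1}^n \max(y_j-y_i,\,0)
\;=\; \gamma_i\,\frac{\mu_i^{+}-y_i}{\mu_Y},$$

with $\gamma_i$ the share of the sample *strictly* healthier than $i$ and
$\mu_i^{+}$ their mean health. Properties the implementation guarantees
(and the test suite checks by brute force):

* **Dimensionless**: $RD$ is unchanged under $y \mapsto cy$, $c>0$.
* **Boundary**: $RD_i = 0$ exactly for persons at the sample maximum.
* **Monotone**: within a sample, $y_i \le y_k \Rightarrow RD_i \ge RD_k$.
* **Transfer principle**: a rank-preserving progressive transfer never
  increases the mean index.
* **Gini identity**: $\overline{RD} = $ Gini$(y)$, to $10^{-10}$ in tests.

Ties are resolved by strict inequality — equals do not deprive each other.
The index requires $\mu_Y > 0$; the oriented scales are bounded below by
positive values except the cognitive screen (0 possible), where a
non-degenerate sample still yields $\mu_Y>0$, enforced as a precondition.
Computation sorts once and uses suffix sums ($O(n\log n)$); the $O(n^2)$
double-sum definition is kept in the tests as the independent oracle.

Two open choices were resolved as follows. The index is computed
**per health dimension** (self-rated health, ADL, iADL, cognition),
matching result tables that report the four outcomes side by side, rather
than as a composite. And it is computed **after** listwise deletion on
each dimension's analysis sample, so $\mu_Y$ refers to the sample actually
modelled. Both choices are revisitable without touching the index itself.

## Health instruments and orientation

* **ADL / iADL**: six items each, responses 1 (no difficulty) to 4
  (unable); the scale score is the item sum, 6–24. A record missing any
  item is incomplete for that scale only (per-dimension listwise
  deletion). The 4-level sum is used (not a binarised difficulty count),
  consistent with the 6–24 range.
* **Cognition**: consumed as a precomputed 0–30 total (higher = better).
* **Self-rated health**: the 5-level ordinal rating (5 = very healthy).

Orientation makes "larger = healthier" global: ADL and iADL are reflected
by $x \mapsto 30-x$ (a self-inverse bijection of 6–24 onto itself); the
other two pass through. With this convention the deprivation index always
measures deprivation *of health*.

## Digital divide indicators

* **Access** = 1 if any of home broadband, $\ge 1$ smart device, or
  $\ge 1$ digital device — a monotone any-of-three rule.
* **Use score** = WeChat + Moments + mobile payment, an integer 0–3,
  defined only when all three items are observed (device non-owners are
  never silently scored 0). Use-level analyses are restricted to the
  eligible subsample.
* **Use binary** (for matching) splits the use score at the sample
  median; ties at the median go to 0. The strict rule is deterministic and
  conservative for the treated group, and the resulting partition depends
  only on ranks.

## The regression model

The deprivation index of one dimension is regressed by OLS on the
exposure and the control block: sex, age, hukou, education dummies
(reference: no formal education), marital status, insurance dummies
(reference: other insurance), chronic disease, disability, monthly
outpatient visits, intergenerational support, log-income, and region
dummies (reference: eastern). Choices that matter:

* **Full standardization.** The outcome and *all* regressors — dummies
  included — are z-scored, so reported coefficients are standardized betas
  comparable across terms, and the exposure beta is invariant to affine
  rescaling of any covariate. This mirrors result tables that print
  standardized coefficients for dummy variables too.
* **Classical SEs.** Homoskedastic OLS standard errors; no
  robust/clustered correction is applied anywhere.
* **Income**: winsorized at the 1st/99th percentiles (the conventional
  bilateral-trimming default, configurable in `trim_and_log_income()`)
  then `log10(x+1)`. The compressed `log10` scale is used because a
  survey-income mean near 0.7 on the log scale is only plausible there
  (income in 10k-yuan units); zero income maps to exactly 0.
* **Listwise deletion per model**: each fit drops cases missing any model
  variable; sample sizes are reported per model.
* **Rank deficiency** is an error naming the offending columns, except in
  subgroup fits (below).

Univariate screening before modelling uses the uncorrected chi-square
test for categorical variables and, for continuous variables, a two-sample
t test when both groups pass Shapiro-Wilk normality (evaluated on at most
5000 values per group — the test's own limit), otherwise the Wilcoxon
rank-sum test; all two-tailed at $\alpha = .05$.

### Moderation and subgroups

Moderation adds the product of the *centered* exposure and *centered*
moderator, so main effects keep their interpretation; a constant moderator
or moderator identical to the exposure is an error. Subgroup analyses
refit the model within levels of sex, the age bands (<60 vs $\ge$60),
hukou, education or region; strata below 50 cases are skipped with a
warning. Inside a stratum a dummy can be structurally constant (the
region dummies inside a region subgroup), so subgroup fits drop constant
columns and record them rather than erroring — the strict error is kept
for full-sample fits, where a constant column signals a data problem.

## Propensity-score-matched sensitivity analysis

The matched analysis treats the digital indicator as a binary treatment
(access as-is; use median-binarised):

1. **Propensity**: maximum-likelihood logit of treatment on the full
   control block. Perfect or quasi-perfect separation (fitted
   probabilities within $10^{-8}$ of 0/1, or non-convergence) is an error
   advising covariate reduction.
2. **Matching**: greedy 1:1 nearest neighbor on the propensity score,
   without replacement, treated processed in descending propensity order;
   distance ties go to the lowest control index. Fully deterministic. A
   caliper is available and off by default.
3. **ATT**: mean within-pair outcome difference; SE and two-tailed p from
   the paired t test. Zero-variance differences are reported as the
   degenerate limit with a warning.
4. **Balance**: absolute standardized mean differences
   $|\bar x_T-\bar x_C| / \sqrt{(s_T^2+s_C^2)/2}$ before (full arms) and
   after (matched sample) matching, flagged at the 20% criterion, plus
   propensity-support ranges and Gaussian kernel density summaries
   (Silverman bandwidth) per arm as summary statistics, not figures.

**A caveat discovered in simulation.** When the arms are near-equal (the
2018-calibrated cohort has ~50% access), 1:1 matching without replacement
and without caliper necessarily consumes (almost) every control, so it
cannot improve balance — and the retained treated skew toward high
propensity. The package's matched *benchmarks* therefore use a caliper of
0.02: in 100-replicate simulations at confounding strength 1, the
no-caliper and 0.05-caliper matches left a residual ATT bias comparable
to the paired-t SE (CI coverage 89%), while 0.02 reduced the bias an
order of magnitude below the SE (coverage 94%) and brought every
confounder's post-match SMD well under 20%. For user analyses the default
stays "no caliper", since the matched-pairs idiom itself does not demand
one; users with balanced arms should set one.

## The synthetic cohort generator

`generate_cohort()` emulates a CHARLS-like older-adult table. What it
reproduces:

* **Marginals per wave** (2018 / 2020): sex, age (gamma-shifted, minimum
  50), marital status, 3-level education, hukou, insurance, chronic
  disease, disability, intergenerational support, 4-level region, income
  (log-normal on the `log10` scale), outpatient visits (negative
  binomial, capped at 30), broadband (~39% vs ~57%), smart/digital device
  ownership, and use items conditional on ownership. Calibration is loose
  (margins within ±5 points), never joint.
* **Confounding**: a standardized index (education +, age −, rural −,
  log-income +) enters both the digital indicators (log-odds shift of
  `confounding_strength` per index SD) and latent health (slope
  `0.5 * confounding_strength`). Centering the index within sample keeps
  the marginal calibration intact as confounding grows.
* **Treatment effect**: latent health $h = 0.5\,c\,\text{idx} + \tau D +
  \varepsilon$, $\varepsilon \sim N(0,1)$, where $D$ is the derived
  access indicator (or access × rural when `tau_rural_only = TRUE`, the
  known-heterogeneity benchmark). $h$ maps *monotonically* onto all four
  instruments: ordinal thresholds for self-rated health, per-item
  binomial difficulty probabilities $\mathrm{logit}^{-1}(a_j - 1.1h)$ for
  ADL/iADL, and a rounded clipped linear map for the cognitive total.
* **"Unknown" use items**: WeChat/Moments/payment are missing exactly for
  persons without a smart device, mirroring the unknown-row pattern of
  survey descriptives; `missing_rate` adds independent item-level
  missingness on top.
* **Determinism**: identical config and seed give byte-identical tables,
  and the session RNG state is restored afterwards.

What it deliberately does **not** reproduce: the survey's sampling design
and weights (no survey weights are applied anywhere in the package),
household structure,
longitudinal linkage, joint covariate distributions, and the heavy
skew/kurtosis of real health-scale distributions. Passing tests therefore
demonstrate that the *estimators* recover known structure under a clean
generative model — not that real-survey estimates are unbiased.

### Calibrating the effect size

The latent $\tau$ maps nonlinearly onto the standardized exposure-RD
coefficient, so `calibrate_tau()` finds, by secant search on 200,000-person
pilot cohorts with a fixed pilot seed (common random numbers keep the
$\beta(\tau)$ curve smooth), the $\tau$ achieving a target standardized
beta. The recovery benchmark targets −0.05 — the magnitude typical of the
adjusted digital-divide coefficients in this literature — and checks the
mean fitted beta over 200 cohorts of n = 2000.

## Pipeline, artifacts, exclusions

`run_pipeline()` sequences generation/ingestion, exclusions, scoring,
divide derivation, deprivation (with univariate screening), models (with
optional subgroups) and PSM, writing CSV/JSON artifacts plus a manifest
(stage, n in/out, seed, package version). No timestamps enter the
artifacts, so a rerun with the same configuration and seed is
byte-identical. Configuration is schema-validated first; unknown keys are
rejected by name. One YAML quirk is handled explicitly: YAML 1.1 parses a
bare `n` key as a boolean, so the reader maps it back.

`exclusion_report()` counts exclusions sequentially (age < 50 first, then
missing key variables) and prints percentages against *both* the initial
sample size (the flowchart convention, which published flow percentages
follow) and the pre-stage denominator, since the two are easy to confuse
and genuinely differ.

## Problem sizes in the test suite

The suite exercises: 200 random vectors (n ≤ 50) against the double-sum
oracle; 1000 null cohorts of n = 500 for the size of the exposure test;
200 cohorts of n = 2000 for effect recovery; 100 confounded cohorts of
n = 2000 each for ATT coverage, balance, and rural-effect heterogeneity.
These sizes give Monte-Carlo error comfortably inside the asserted bands
while keeping the default run in tens of seconds.

## Known limitations

* The generator's health margins are matched loosely; it is a test bed,
  not a population emulator.
* Classical SEs understate uncertainty under heteroskedastic deprivation
  outcomes; the type-I-error simulation shows the size is nevertheless
  near nominal under the generator's conditions.
* Greedy matching is order-dependent by design (deterministic), not
  optimal matching; with near-equal arms it requires a caliper to be
  selective.
* Self-rated health enters as an interval-scaled 1–5 score, as in the
  source analysis; an ordinal treatment is out of scope.
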