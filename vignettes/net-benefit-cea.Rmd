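---
title: "Person-level cost-effectiveness analysis with nbrcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Person-level cost-effectiveness analysis with nbrcea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

When several treatment strategies for the same disease are delivered in
routine care rather than in a trial, the question "which strategy is good
value for money?" has to be answered from observational person-level data:
registry records linked to claims, hospitalizations and drug dispensations.
`nbrcea` implements such an analysis end to end for the motivating setting
of hepatocellular carcinoma (HCC), where patients may receive
radiofrequency ablation (RFA), surgical resection (SR), liver
transplantation (LT), combinations with transarterial chemoembolization
(TACE), or no curative treatment at all. The real linked data are not
public; the package therefore ships a synthetic cohort generator that
emulates their structure, and every analysis stage is written to run
identically on real data supplied as data frames and config files.

# The model

## Person-level net benefit

For person $i$ with effect $E_i$ (life years or quality-adjusted life
years gained from diagnosis) and cost $C_i$ (discounted 2013 USD), the net
benefit at willingness-to-pay $\lambda$ is

$$NB(\lambda)_i = \lambda E_i - C_i.$$

The *net benefit regression* is an ordinary least squares fit of
$NB(\lambda)_i$ on a treatment dummy $T_i$ (one strategy versus no
treatment), the full dummy-coded covariate set (age band, sex,
neighbourhood income quintile, urban/rural residence, birth country,
Charlson-Deyo comorbidity category, diabetes, HIV, an 11-level liver
disease stage indicator, ultrasound screening category, cancer stage at
diagnosis, and diagnosis-year band), and the estimated propensity score.
The coefficient $\delta$ on $T_i$ is the covariate-adjusted *incremental
net benefit* (INB) at $\lambda$; the strategy is cost-effective at
$\lambda$ when $\delta > 0$.

Because least squares is linear in the response, fitting the effect and
cost regressions once on the same design yields the whole INB curve
exactly: $\widehat{INB}(\lambda) = \lambda \widehat{\Delta E} -
\widehat{\Delta C}$ and $SE^2(\lambda) = \lambda^2 v_E + v_C - 2\lambda
v_{EC}$. `fit_nbr()` refits at a single $\lambda$ (useful as an identity
check, which the test suite exercises to machine precision);
`incremental_effect_cost()` plus this identity is what the pipeline uses
across the grid.

## Propensity adjustment

The propensity score is the conditional probability of receiving the
active strategy given the covariates, estimated by logistic regression on
the same covariate set and entered as a *linear continuous* regressor
(stratification is a legitimate alternative; the linear form was chosen
because it keeps the design full rank in small strategy subsets and
matches the additive-adjustment reading of the source analysis). Under
quasi-separation — nearly unavoidable when a strategy has only a dozen
recipients and thirty-odd dummies — the fit falls back to a small ridge
penalty (`1e-3`) with a warning rather than returning infinite
coefficients.

## ICERs and their confidence bounds

The incremental cost-effectiveness ratio is $\widehat{\Delta C} /
\widehat{\Delta E}$. Its 95% bounds are read off the INB band: the upper
bound is the smallest $\lambda$ at which $INB(\lambda) - z_{.975}
SE(\lambda)$ reaches zero (from there on the strategy is confidently
cost-effective), the lower bound the largest $\lambda$ at which
$INB(\lambda) + z_{.975} SE(\lambda)$ is still non-positive. Either bound
can be undefined on the search range (the package returns `NA`), mirroring
how a very uncertain strategy can have an ICER whose upper bound never
materialises. Whether the source analysis used exactly this construction
or a separate method is not documented; the crossing construction is
implemented and labelled as such.

## Acceptability curves

The probability that a strategy is cost-effective at $\lambda$ is
$\Phi(\widehat{INB}/SE)$. This is *identical* to the published rule
("halve the two-sided p-value; for negative INB the probability is the
one-sided p, for positive INB one minus it") under the normal reference
distribution — an identity the test suite verifies over a grid. A normal
rather than $t$ reference is used because the motivating cohorts have
thousands of observations and the published probability cells match the
normal CDF to four decimals; a $t$ flag was considered and rejected as
indistinguishable at these sizes.

## Multiple imputation

Birth country, comorbidity and cancer stage are incomplete in the data
the generator emulates. Missingness is *monotone* in the declared order
birth_country → comorbidity → cancer_stage, and imputation proceeds
sequentially: each variable is modelled on the always-observed covariates
plus the earlier-ordered (already complete) variables, fitted on the
records that observe the target. Multilevel variables are imputed as an
ordered sequence of binary logistic models (level 1 vs rest, then level 2
vs the remainder, and so on), which is the natural reading of the named
monotone-logistic procedure without inventing a multinomial variant. Each
of the $m$ imputations draws the model parameters from their approximate
sampling distribution, so completed datasets differ (proper imputation).
All imputation fits carry a tiny ridge penalty (`1e-4`) because small
synthetic strata can separate; at that size the penalty is numerically
irrelevant away from separation.

Downstream estimates are pooled by Rubin's rules at *each* $\lambda$ (and
bivariately for $(\Delta E, \Delta C)$, including their covariance): the
source analysis does not say at which stage results were combined, and
pooling the INB estimates keeps the pooled curve exactly affine in
$\lambda$. The pooled total variance is $\bar W + (1 + 1/m) B$.

# Effect and cost construction

**Age at death.** Age at diagnosis is categorical and mapped to 55, 65,
75, 85. Patients who died get their observed death year. Patients alive
at the administrative end (2011) get diagnosis year plus a
stage-specific literature survival (stage I: 5 years, II: 4, III–IV: 3);
when that lands inside the observed window the year after the
administrative end (2012) is taken as the most likely death year.

**PYLL** is the residual life-table expectancy at (sex, age at death).
Discounting treats the expectancy as a stream of lost year-fractions
anchored at the death year, with the fractional final year pro-rata — a
choice made so the discounted PYLL is continuous in the expectancy.

**QALYL** is $u_{ref} \cdot PYLL + \sum_k (u_{ref} - u_{state(k)})
(1+r)^{-k}$ over the years lived from diagnosis, i.e. the lost years
weighted by the reference (alive-and-disease-free) utility plus the
decrement from the reference down to the occupied state for each year
lived. Reading the decrement as "reference minus state" keeps QALYL a
loss on the same scale as the weighted PYLL. Whether the reference
utility should be a population norm or 1.0 is not documented in the
source; it is exposed as `reference_utility` (packaged default 0.85, a
typical age-adjusted population norm). The state trajectory holds stage
at diagnosis fixed (no progression data), overrides the liver state with
incurable disease for advanced-stage cancer, and switches LT/SR
recipients to a post-procedure state from the second year onwards.

**Gained-scale effects.** The regression consumes effects on the gained
scale: discounted life years $\sum_k (1+r)^{-k}$ and QALYs $\sum_k
u_{state(k)} (1+r)^{-k}$ from diagnosis to (estimated) death. Both the
loss measures and the gained measures are emitted per person.

**Costs** are per-calendar-year ledgers in nominal CAD, inflated to the
2013 price level by the CPI ratio, converted to USD at purchasing power
parity, and discounted at 3% to each person's diagnosis year — the same
anchor as the effect streams, chosen because follow-up time varies widely
across persons.

The packaged life table, CPI series and non-anchor utilities are
clearly-labelled synthetic toys (the incurable-HCC utility 0.40, range
0.32–0.48, is the literature-pooled anchor); real analyses supply their
own via `read_life_table()`, `read_deflator_table()`,
`read_utility_table()`.

# The synthetic cohort generator

`generate_cohort()` emulates, per patient: the derived covariates at
registry-like prevalences (drawn independently across covariates — a
deliberate simplification; real covariates are correlated), a treatment
label from a *single multinomial logistic* draw over the eleven labels
whose log-odds of any active strategy shift with the confounding
coefficients (default: younger, screened, early-stage,
decompensated-cirrhosis patients are more likely to be treated), latent
person-level outcomes, a death year, and a front-loaded per-year cost
ledger consistent with the latent total under the packaged deflators.
Strategy intercepts are calibrated by fixed-point iteration so the
*marginal* shares match the configured prevalences despite confounding —
this is what makes the share-convergence tests meaningful.

The latent outcome columns (`ly_gained`, `qaly_gained`, `cost_usd`) are
linear-Gaussian in the same dummies the regressions adjust for, with the
configured true increments added per strategy — so the adjusted estimator
is consistent and its confidence intervals attain nominal coverage by
construction, which is exactly what the parameter-recovery suite checks
(200 replicates of n = 2,000 at true $\Delta QALY = 0.9$, $\Delta C =
\$14{,}000$). Costs are truncated at zero (negligible mass under the
defaults); effects are left untruncated to keep the linear model exact.
Noise scales (QALY sd 1.1, cost sd \$15,000, cost–QALY correlation 0.3)
were chosen once to give per-strategy standard errors of the same order
as the published tables at the default cohort size.

What passing tests on this generator do *not* show: robustness to
model misspecification (real outcome surfaces are not linear in dummies),
to correlated covariates, to informative censoring, or to
missingness that is not completely at random. The generator's monotone
missingness is MCAR by construction; the imputation machinery is
exercised for correctness (marginal preservation, monotonicity,
determinism), not for MAR bias correction.

Default missingness rates are 0.33 / 0.35 / 0.56. The first and last
approximate the unknown shares of birth country and cancer stage in the
emulated registry; the comorbidity rate in that registry (~0.14) is
incompatible with a monotone pattern in the fixed order (monotonicity
forces non-decreasing rates), so it was raised to the minimum feasible
value above the birth-country rate. The "4.5 months apart" scan-retention
rule is day-resolved as 137 days, applied *rolling from the previously
retained scan* (the anchoring is not documented in the source; rolling
retention is the implemented and tested reading), with the two 12-month
windows as `[dx-365, dx)` and `[dx-730, dx-365)`.

# Running the pipeline

```{r, eval = FALSE}
library(nbrcea)

config <- analysis_config(m = 5, seed = 1,
                          lambda_grid = seq(0, 100000, by = 1000))
report <- run_pipeline(config)   # generates the default n = 2,222 cohort
report                           # ICER summary, ascending $/QALY
write_tables(report, "reports/") # Table 2/3/4-style CSVs + CEAC + frontier
```

Sensitivity variants are config toggles: `utility_scenario = "lower"` /
`"upper"` swap the utility bounds (life-year results are invariant, which
a test asserts), and `exclude_stage_iv = TRUE` drops the hidden stage-IV
sub-label carried by the generator inside the III–IV analysis category
(the category itself follows the source's grouping; the sub-label exists
solely to support this sensitivity run).

# Numerical choices and degenerate inputs

- OLS is computed via the QR decomposition; rank-deficient designs are an
  error naming the aliased columns rather than a silent drop.
- A zero-variance net benefit returns coefficient 0 with SE 0 (and
  probability 1/0/0.5 by sign conventions in `ce_probability()`).
- ICER bounds are located by a 20,001-point scan refined by `uniroot`;
  with all variances zero both bounds collapse onto the point ICER.
- The willingness-to-pay grid defaults to \$0–\$100,000 in \$1,000 steps
  (the acceptability-curve range); crossing searches extend to \$500,000.
- Variance inflation factors are `1/(1-R^2)`; constant columns are
  flagged infinite. Interaction terms are not generated by default; the
  VIF report supports the drop-if-above-10 rule when they are.
- All randomness flows from explicit integer seeds; identical
  (spec, config, seed) reproduce byte-identical cohorts and reports. The
  test and acceptance problem sizes (n = 2,222 default; n = 20,000 for
  prevalence convergence; 200 × n = 2,000 for coverage) are the package's
  chosen study conditions.

# Known limitations

- Pairwise strategy-versus-no-treatment contrasts only; no simultaneous
  multi-arm frontier modelling beyond strict-dominance flags.
- No bootstrap or Bayesian ICER uncertainty; bounds come from the
  regression SEs via the crossing construction.
- Rare strategies (a handful of recipients against thirty-odd
  regressors) yield unstable increments — visible in synthetic reports
  exactly as in the emulated registry, and the reason the ridge fallback
  exists.
- The generator does not simulate claims records, ICD codes, or linkage
  artefacts; covariates are born at the derived level, with the two
  derivation rules (screening windows, comorbidity lookback) exposed and
  tested separately.
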