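---
title: "Estimating contact coverage from routine service-utilisation reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating contact coverage from routine service-utilisation reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactcov)
```

## The estimand and its data

Contact coverage is the proportion of people who have a disorder in a
12-month period and who, in that period, had at least one contact with a
relevant health service. For severe mental disorders — non-affective
psychosis, bipolar disorder and moderate-severe depression — population
surveys measure this well but are too expensive to repeat routinely. The
alternative pursued here is to divide what routine health information
systems report (counts of treated cases in specialist inpatient and
outpatient facilities) by the expected number of prevalent cases
(prevalence × population). That ratio is only meaningful after a series
of validity screens and adjustments, because routine reports are
incomplete, double-count people seen in both settings, and sometimes
record visits where cases were requested. This package implements the
full chain: screens, de-duplication, case-definition adjustment,
delta-method uncertainty, plausibility filtering and random-effects
pooling.

## The estimator chain

**Treated cases.** A record contributes only if it reports utilisation in
*both* settings and the representativeness of its reporting system. The
visits-per-case screen then drops reports whose pooled visits divided by
pooled cases fall strictly below 1: a treated case implies at least one
visit, so such reports cannot be counts of people. The ratio is computed
on pooled inpatient+outpatient totals rather than per setting, since the
screen targets the overall bookkeeping of a reporting system, not one
facility type; records reporting no visit counts at all pass with a
warning — a screen on reported visits cannot fire without visits.

**Double counting.** Countries are classified by which setting treats the
majority of reported cases (ties go to outpatient-prioritised, the
conservative side, because that branch applies the de-duplication). In
outpatient-prioritised systems every inpatient is assumed to also appear
in the outpatient tally with probability given by the follow-up item: the
share of discharged inpatients seen in outpatient care within a month,
reported in four bins (≤25%, 26–50%, 51–75%, >75%). The bins contribute
their midpoints — 0.125, 0.38, 0.63, 0.875 — and the expected overlap
`midpoint × inpatient` is subtracted from the outpatient count. If that
subtraction turns the outpatient count negative the raw value is used and
the record flagged. Missing follow-up categories are imputed with the
median *midpoint* (not median category — the median should live on the
scale the formula consumes) among reporters in the same GBD region,
falling back to the global median with a warning. For
inpatient-prioritised systems no adjustment is defined; unique cases are
taken as the plain sum of the two tallies, which over-counts any overlap
there — a documented choice, since an inpatient-dominated system offers
no follow-up-based handle on the overlap. Fractional unique cases are
never rounded; everything downstream is a proportion.

**Expected cases.** Prevalence inputs arrive on the scale prevalence
studies publish and are converted to the scale services report against:
schizophrenia prevalence is divided by 0.49 (the schizophrenia :
non-affective psychosis prevalence ratio); depression point prevalence is
multiplied by a point-to-12-month factor and by the combined moderate
(0.17, 95% CI 0.13–0.22) + severe (0.10, 95% CI 0.03–0.20) severity
split, because mild depression is rarely treated in specialist services;
bipolar inputs are already 12-month. The expected count is the adjusted
rate times the *covered* population — population × representativeness.
Applying representativeness to the denominator (rather than inflating the
numerator) leaves the coverage ratio unchanged but keeps both counts
interpretable as quantities within the reporting system's catchment; the
source methodology never states which convention it used, so this one is
documented rather than asserted.

**Uncertainty.** Four standard-error steps: binomial SE for the treated
prevalence; normal-interval reconstruction `(upper − lower)/3.92` for the
prevalence input; the independent-ratio delta method for coverage; and
the delta method again for the logit, `se_logit = se_c / (c(1 − c))`.
Country CIs are the inverse logit of `logit(c) ± 1.96 se_logit`, which
respects the (0, 1) range.

**Pooling.** Included countries are pooled on the logit scale with
DerSimonian–Laird random effects, per disorder, by income group, WHO
region, GBD super-region and overall. DL was chosen over REML because it
is closed-form and therefore exactly checkable against an independent
hand implementation (and against `metafor`, which the test suite does);
the estimator is isolated in `dl_random_effects()` so an alternative can
be slotted in. Baujat coordinates (contribution to Q on x, leave-one-out
influence on y) are computed with fixed-effect weights throughout — the
classic definition — and are reported, never acted on: influential
countries are retained, and the plot is for inspection.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `schiz_to_psychosis_ratio` | 0.49 | ratio of prevalences | literature-derived constant |
| `depression_moderate_prop` / `severe_prop` | 0.17 / 0.10 | proportions | severity split of depression prevalence |
| `depression_point_to_12m_factor` | 1.30 | ratio | **placeholder** — the underlying coefficient is not published; any user with access to the original regression should override it |
| `visits_per_case_min` | 1 | visits/case | a case implies ≥ 1 visit |
| `divergence_limit` | 0.30 | relative difference | "dramatically different" reported vs UN population is undefined at source; 0.30 is conservative, transparent and logged |
| thresholds table | shipped YAML | proportions | reconstructed from published survey-based service-use figures; editable configuration, not measurements |
| `conf_level` | 0.95 | — | convention |

The severity split carries its own uncertainty; the combination rule
treats the combined split as fixed for the central rate and adds its
relative SE (reconstructed from the two intervals, combined in
quadrature) to the prevalence's relative SE. No combination rule is
stated at source; this is the simplest symmetric choice and lives in one
function (`split_relative_se`) for replacement.

## Numerical choices and degenerate inputs

* Coverage ratios at or above 1 are capped at 0.999 with a warning
  rather than excluded: the plausibility thresholds, not the cap, are the
  exclusion mechanism, and the logit needs `c < 1`.
* Proportions at exactly 0 or 1 entering the logit receive the standard
  continuity correction `1/(4n)` with `n` the effective population.
* A zero-cases report with visits present fails the visits-per-case
  screen (the ratio is undefined, which itself signals inconsistency).
* `tau² < 0` truncates to 0, where DL reproduces fixed-effect pooling
  exactly; a single-country group passes through with its own CI and
  `tau² = 0`.
* Empty CSV cells parse to `NA`, never 0 — a reported zero is a
  legitimate report and is kept.

## The synthetic world

`simulate_atlas_cohort()` emulates the *structure* of a reporting round,
not the 2017 country distribution. Per country it draws: income group and
regions; a true prevalence (log-normal, SD 0.2 on the log scale, around
0.5% for psychosis, 0.6% for bipolar, 1.2% for moderate-severe
depression); a true coverage (logit-normal, SD 0.8, around income-group
means of 10.9/21.5/29.2/59.5% for psychosis, 3.1/3.5/3.1/10.4% for
bipolar, 2.9/4.3/13.0/31.1% for depression — the gradient an Atlas-style
exercise reports); a true follow-up fraction (uniform); and a
representativeness (uniform 0.5–1). Treated persons are drawn binomially
from the covered population and split between settings; each inpatient
reappears in the outpatient tally with the follow-up probability — the
patient-level mechanism whose exact unique count is the oracle for the
de-duplication formula. Per-case visit rates are `1 + Gamma(2, 3)`, so a
clean reporter can never trip the visits screen. Prevalence inputs are
emitted back on the schizophrenia / all-severity-point scales so the
pipeline's adjustments must undo them exactly. The default
reporting-quality mix (28% clean, 12% visits-mistaken-as-cases, 60%
incomplete) mirrors the attrition of a real round; corrupted reporters'
visit volumes are scaled so their implied coverage provably exceeds 1,
guaranteeing the threshold filter sees them wherever an upper bound
exists (psychosis deliberately has none).

What passing tests therefore show: the screens fire exactly on the
records constructed to deserve them; the de-duplication formula tracks a
patient-level registry to well under 2% mean absolute relative error;
country estimates are unbiased for the generator's truth to well under 1
percentage point; and the pooling reproduces independent implementations
to 1e-10. What they do not show: robustness to misdiagnosis, to
non-binomial reporting error, to correlation between coverage and
prevalence, or to real-world deviations from the "all inpatients are
followed up into the outpatient tally" assumption — none of which the
generator models.

## Problem sizes

The shipped experiments use 1,000 simulated countries for the
double-counting oracle, a 99-point grid plus 10,000 Monte-Carlo draws for
the delta-method audits, and 500 replications of an 80-country,
4-income-group world (clean reporters, thresholds open, psychosis
definition) for parameter recovery — sizes at which every Monte-Carlo
standard error is far below the property bands being checked.

## Known limitations

* **Pooled CIs under-cover at high coverage.** In the recovery
  experiment the DL 95% CIs contain the true group coverage in roughly
  90% of replications rather than 95%, and the shortfall concentrates in
  the high-coverage group. The mechanism is intrinsic to inverse-variance
  pooling of logit proportions: the delta-method logit SE grows as
  `1/(1 − c)`, so the claimed SE correlates with the estimate itself —
  high-coverage countries are downweighted (pulling the pooled logit
  down) and the weighted Q statistic understates between-country
  heterogeneity. A z-quantile interval with ~20 countries per group is
  also slightly anti-conservative on its own. Pooled intervals should
  therefore be read as mildly optimistic, particularly for high-income
  psychosis-type groups; a Knapp–Hartung-style t interval or
  arcsine-scale pooling would be natural extensions behind the same
  interface.
* The point-to-12-month depression factor is a placeholder (above);
  absolute depression coverage levels inherit its error multiplicatively.
* The threshold table is reconstructed configuration; with different
  bounds the included-country set, and hence pooled estimates, change.
* For inpatient-prioritised countries the unadjusted sum over-counts any
  true overlap; coverage there is biased upward by up to the follow-up
  fraction times the inpatient share.
* Binning the follow-up fraction into four categories adds bounded
  (±0.125) error to the overlap correction for individual countries; it
  is mean-zero by construction across countries.
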