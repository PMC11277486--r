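---
title: "Modeling blow fly development: stage-transition curves and validated degree-day models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling blow fly development: stage-transition curves and validated degree-day models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phormiadev)
```

## The scientific problem

Forensic entomologists estimate a minimum postmortem interval from the age
of blow fly immatures collected on remains. Age is inferred by comparing a
specimen's developmental stage against laboratory development data, and
because insect development rate depends strongly on temperature, the
comparison is made on a *thermal* clock: within the linear portion of the
rate-temperature response, completing a given developmental event requires
a fixed number of accumulated degree-days (ADD) above a developmental
minimum, whatever the temperature history. A linear degree-day model for an
event therefore consists of a developmental minimum (the x-intercept of the
rate-temperature regression, in °C), an ADD requirement (the reciprocal
slope, in degree-days), and — crucially for casework — the temperature range
over which the linear approximation actually holds.

`phormiadev` implements this chain for the black blow fly *Phormia regina*,
from raw destructive-sampling stage counts to validated degree-day models,
together with a synthetic cohort generator that emulates the experimental
design under which the species' reference data were collected. Development
is tracked through egg (E), three larval stages with the third split into
feeding (L3f) and post-feeding migratory (L3m) phases, pupa (P), and
adult (A).

## The data structure and its simulation

The emulated experiment rears cups of 20 eggs at eleven constant
temperatures (7.5–32.5 °C in 2.5 °C steps). Sampling is destructive: at
each scheduled time one cup per replicate (four incubators) is pulled and
every individual is staged morphologically; pharate individuals count as
the stage they have not yet molted out of. Sampling times are scheduled per
stage boundary by converting prior transition-time ranges to accumulated
degree-hours above an assumed 10 °C minimum, rescaling them to each
temperature, and dividing each window into five equal times
(`build_sampling_schedule()`); temperatures at or below the assumed minimum
reuse the schedule of the lowest temperature above it, since thermal time
cannot be scaled below the assumed zero.

`generate_cohort()` places individual variation on *physiological-time
thresholds*: each individual draws its per-stage ADD requirement from a
normal distribution with mean equal to the stage's true ADD and standard
deviation `transition_cv` times that mean (truncated positive). Transition
*times* at any temperature are then normal with spread proportional to
stage duration — the defining empirical feature of real cohorts, in which
the long post-feeding and pupal stages show the largest variation. Default
parameters are the emulated study's conditions: stage ADD requirements
(8.4, 12.1, 14.4, 29.3, 30.2, 84.9 degree-days for E…P), a true
developmental minimum of 10.2 °C, and a 5% threshold CV, a level consistent
with the few-percent spread of the published per-temperature accumulations.

The rate-temperature response is linear, `(T - true_dev_min)` degree-days
per day, inside `linear_range` (default 15–32.5 °C). Outside it the rate is
multiplied by an attenuation that ramps to zero at the biological minimum
(`biological_min`, default 11 °C — development *ceases* there, unlike the
developmental minimum, which is a regression parameter):
`g = ((T - biological_min)/(linear_lo - biological_min))^curvature_strength`
below the range, with the mirrored ramp above it using the same
characteristic width. The exponent defaults to 1 (linear collapse); 0
switches curvature off entirely. A weak perturbative attenuation would be
both biologically implausible 1.5 °C above the point where development
stops and statistically invisible to the diagnostics described below, so
the collapse form is the default. Mortality is an optional independent
per-stage Bernoulli per individual (default 0, matching the absence of
temperature-associated mortality in the reference data).

What the generator does *not* emulate: genetic heterogeneity between cups,
diet and density effects, incubator temperature drift, staging
misclassification, and any correlation between an individual's successive
stage thresholds. Tests passing on synthetic cohorts therefore demonstrate
that the estimation chain is correct under the stated stochastic model, not
that the model exhausts real biological variation.

## Stage-transition curves

Proportion-in-stage versus time at one temperature is described by four
curves (`evaluate_curve()`): a Gaussian for short stages; a modified
Gaussian `a*exp(-1/2*|(x-b)/c|^d)` whose exponent `d > 2` produces the flat
top seen when a long stage holds the entire cohort between transitions; and
cumulative / reversed-cumulative Gaussians (`erf` forms) for the sigmoidal
rise of adults and fall of eggs. `select_larval_model()` chooses the
modified form when at least `k = 3` consecutive points lie within 5% of the
series maximum. Fitting (`fit_stage_curve()`) is bounded Levenberg–
Marquardt least squares with moment-based starts (`a` from the series
maximum, `b` from the peak or the interpolated 50% crossing, `c` from the
half-width or crossing bracket, `d = 2`), a ladder of spread starts to
escape the flat-gradient region far from the grid resolution, and bounds
`a <= 1.05` × the unit ceiling (1 or 100 — the observed maximum would be too
tight when a plateau is never sampled), `c <=` the x-range, and
`d` in (0.5, 10] to prevent plateau-exponent blow-up. Degenerate (constant)
series are refused, and non-convergence is flagged, never silently
returned.

## 50% transition times

Stage duration is defined as the time between 50% transition *into* and
50% transition *out of* a stage, because the 50% point carries a standard
error, which peak-to-peak definitions do not. Two routes estimate it:

* **Probit** (`probit_t50()`): maximum-likelihood probit regression of
  "already past the boundary" on time; `t50 = -intercept/slope`, its
  standard error by the delta method, and any other percentile through the
  fitted quantile function.
* **Cumulative Gaussian** (`estimate_t50()`, the degree-day default): the
  entered-stage proportion — individuals *at or past* the later stage, so
  every sampling time at the temperature contributes — is truncated to the
  first portion of the rise and fit with the cumulative Gaussian, its
  plateau fixed at 100% since every surviving individual eventually
  transitions; `t50` is the fitted center `b`. Deaths are excluded from all
  denominators.

Both routes estimate the median of the same normal transition-time
distribution and agree within sampling error; the report records which
route produced each number. Three numerical policies matter:

* **Bracketing.** A median is only estimated when observed proportions
  cross 50%. Anything less would be an extrapolation; in practice this rule
  is what removes temperatures whose development fell so far behind the
  ADH-scaled schedule that the transition was never observed — exactly the
  empty low-temperature cells of the published tables.
* **Identifiability fallback.** Least squares cannot separate `b` and `c`
  when the rise contains fewer than two partial points (the Jacobian
  columns are proportional); such series fall back to the probit fit, which
  draws real information from the binomial 0/n and n/n observations.
* **Degenerate steps.** A noiseless series that jumps 0 → 100% between
  consecutive times yields the bracket midpoint with standard error
  `gap/sqrt(12)`; the estimator's resolution is then the sampling interval,
  which is why the package's noiseless ground-truth checks use densely
  sampled schedules.

`stage_durations()` subtracts consecutive 50% points (the egg stage runs
from oviposition, so egg duration *is* the first boundary's t50, and the
egg-stage ADD is identically the E–L1 transition ADD). Missing boundaries
yield missing durations, never interpolated, and a non-monotone t50
sequence is an error naming the offending pair.

## Validated degree-day models

For each of twelve events — six cumulative transitions (E-L1 … E-A, time
from oviposition) and six stage durations (E … P) — rates in 1/days are
regressed on temperature (`rate_regression()`; unweighted OLS, as no
weighting scheme is part of the method). The model then passes through an
iterative validation loop (`fit_degree_day_model()`):

1. **Runs-test pruning** (`prune_until_linear()`): while the exact
   Wald–Wolfowitz runs test on the temperature-ordered residuals rejects at
   `alpha = 0.05`, remove one endpoint temperature per iteration — the end
   with the larger absolute standardized residual, ties toward the low end
   where proximity to the biological minimum bends rates hardest. Endpoints
   only: thermal non-linearity lives at the extremes, and endpoint-only
   removal keeps the valid range contiguous. One point per iteration gives
   a deterministic, auditable trace.
2. **Accumulation validation** (`validate_add_accumulation()`): the core
   degree-day assumption is that `ADD_i = duration_days_i * (T_i - dev_min)`
   is *constant* across included temperatures. The accumulations are
   regressed on temperature and the model is accepted only when the slope's
   t-test is non-significant **and** the runs test shows no pattern. This
   catches residual curvature and — because a misspecified minimum tilts
   the accumulations linearly — errors in the x-intercept itself.
3. On failure, the worse endpoint is excluded and the loop repeats from
   step 1, until acceptance or fewer than three points remain (an error
   carrying the full exclusion trace).

`alpha = 0.05` is used for both tests; the runs test is exact (closed-form
conditional distribution, cross-checked against brute-force enumeration)
up to n = 20 and normal-approximated with continuity correction above.
Since treatments are constant temperatures, accumulations are computed as
`duration x (T - dev_min)` directly; no hourly integration is needed.
Cross-temperature summaries report the calculated ADD mean, its spread as
the *population* standard deviation (divisor n, matching the convention of
the published reference table), and the percent deviation from the
regression ADD.

### A known diagnostic limitation

With roughly ten temperatures, sign-based and slope-based diagnostics have
a blind spot: a *single* grossly curved endpoint among otherwise clean
points cannot be rejected by the runs test (the minimum attainable
two-sided p at n = 9 with one endpoint run is about 0.14), and the
accumulation slope t-statistic is invariant to the outlier's magnitude
(the outlier inflates the residual variance in proportion to the slope it
creates; p ≈ 0.13 regardless of size). Masked retention of one curved
low-temperature point is therefore possible for early boundaries. In the
emulated design this is largely moot — strongly curved temperatures
overshoot their sampling windows and are refused by the bracketing rule
before any regression sees them — but users applying the loop to externally
supplied rate tables should inspect the per-temperature accumulations
(`model$validation$add_values`), where such a point is obvious.

## Orchestration, reporting and reference data

`run_pipeline()` chains everything deterministically: entered-stage series
→ t50s → durations → twelve validated models → report tables, logging every
refusal and exclusion with its temperature and reason. The report includes
a percent-time-in-stage table (each stage's share of total egg-to-adult
time, with a column-mean row over complete rows) and a degree-day table
(event, developmental minimum, ADD, r², n, valid range, calculated
mean/spread, percent deviation). `read_observations()` /
`write_observations()` handle the long CSV schema (and XLSX through
`readxl`, with wide stage-column layouts melted automatically and a
column-mapping hook for non-standard headers, since archived workbook
layouts vary).

The package ships three small published reference tables for *P. regina*
(`pr_reference_percent_time()`, `pr_reference_add()`,
`pr_reference_models()`) used as desk-scale cross-checks: the summary rows
(calculated ADD means, population SDs, percent-time column means) are
recomputed by the package's own summary functions, and
`pr_reference_rates()` inverts the printed per-temperature accumulations
back to rates so the published egg-hatch regression can be re-derived end
to end. The inversion is exact only when an event's printed cells are
internally consistent with its printed regression line; the egg-hatch
event is, and is the one used for cross-checks, while some later events'
printed cells embed scatter that the inversion cannot remove.

## Problem sizes used in the test suite

Noiseless ground-truth checks use a dense schedule (200 sampling times per
stage boundary, one replicate) so that the step-resolution of the
degenerate t50 estimator is far below the three-significant-figure target;
parameter-recovery and curvature-exclusion properties use 200 independent
cohorts each under the full emulated design (five times per boundary, four
replicates, 20 eggs). At those sizes the whole suite completes in a few
minutes on one core.

## Limitations

Beyond the diagnostic blind spot above: no curvilinear development models
(the attenuation in the generator exists to *test exclusion*, not to be
estimated); no fluctuating-temperature accumulation; no interval-censored
survival formulation of the transition times; and no hierarchical pooling
across temperatures. The stage-to-age inference used in casework (placing
an unknown specimen's age distribution given its stage) is out of scope —
this package produces the validated thermal constants such methods consume.
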