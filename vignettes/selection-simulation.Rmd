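---
title: "Simulating GP-trainee selection under missing outcomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating GP-trainee selection under missing outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

A selection process can only be evaluated on those it selected. For GP
specialty training, every application carries Stage 2 test scores (Clinical
Problem Solving and Professional Dilemmas), but Stage 3 Selection Centre
scores exist only for applicants above the Stage 2 cut scores, and training
outcomes — LTFT/OOP spells, ARCP Outcome 4 (release from training) and the
date of GP Registration — exist only for appointed trainees. Comparing
selection policies therefore requires estimating, for every application,
the outcomes that *would* have been observed had it been selected.

`traineesim` treats this as a missing-data problem and attacks it with
multiple imputation: build M completed copies of the cohort, run each
candidate selection process on every copy, and pool the resulting 3- and
5-year registration counts as mean (SD) across the M copies. The SD across
imputations acts as a standard error; the empirical 2.5th/97.5th
percentiles give approximate 95% bounds.

The unit of analysis is the *application*, not the doctor: a doctor may
apply in several years, and training outcomes attach (by exact GMC-number
linkage) only to the accepted application.

## Outcome definition

Time to GP Registration is measured in full-time-equivalent (FTE) months:

```
fte = (calendar - oop - ltft) + ltft / 1.67
```

OOP months are subtracted entirely; LTFT months are scaled by 1/1.67,
equivalent to working at 60% FTE (a common value is assumed because actual
FTE fractions are unavailable). We read the "1.67 per year LTFT" rule as
linear per month rather than compounding per whole year — the two coincide
at the 60%-FTE interpretation. A recruit counts as registering within three
(five) years when not released from training and `fte <= 38` (`<= 62`)
months: 36 (60) months plus a 2-month grace period for processing delays.
Thresholds are inclusive, and the grace is applied to both horizons (the
source attaches it to "expected time to registration", which is
horizon-independent); both choices are configurable through
`fte_thresholds()`. An *extension* is a registrant needing more than the
3-year threshold, so extension counts are `reg_5y - reg_3y`. Released
trainees (ARCP Outcome 4) count toward neither horizon and have FTE time
*structurally absent* — a rule enforced everywhere, including inside the
imputation chain.

## The imputation engine

`impute_cohort()` implements fully-conditional-specification (chained
equations) imputation. Seven variables are imputed — withdrawal before
Stage 3, Stage 3 total score, offer accept/decline, LTFT and OOP
indicators, ARCP Outcome 4, and FTE time to registration — using the
always-observed predictors (round, both Stage 2 scores, gender, ethnicity,
UK/non-UK primary medical qualification) plus the other chained variables.

Per imputation: missing cells are initialised by draws from the observed
margins, then the chain cycles `n_iterations` (default 10) times over the
variables, refitting each conditional model on currently-complete data and
redrawing that variable's missing cells.

* **Binary variables**: logistic regression fitted by IRLS; coefficients are
  drawn from the asymptotic posterior `N(beta_hat, (X'WX)^-1)` before
  prediction, so imputation uncertainty is propagated. If the fit fails to
  converge, produces non-finite or extreme coefficients, or the information
  matrix is singular, the model is refitted with a ridge penalty and the
  event is logged in the returned `events`.
* **Continuous variables** (Stage 3 total, FTE time): Bayesian linear
  regression (`sigma^2` from a scaled inverse-chi-squared draw, coefficients
  from their conditional normal) followed by type-1 predictive mean
  matching with a donor pool of 5: each missing case receives the observed
  value of one of the 5 donors with closest predicted mean. PMM keeps every
  imputed value inside the observed support — no negative durations, no
  impossible scores.

Design choices a maintainer should know:

* **Variable order** follows the causal sequence of the training pathway
  (withdrawal → Stage 3 score → offer decision → LTFT → OOP → release →
  FTE time); it is configurable and, at 10 cycles, results are insensitive
  to it.
* **Stage 3 competency** is needed complete by the cut-score selection
  process but is not one of the seven imputed variables (only the Stage 3
  *total* is). It is completed inside the chain as a dependent auxiliary — a
  logistic model visited immediately after the Stage 3 total — rather than
  derived by thresholding the total, because the competency outcome is
  categorical and only correlated with the total.
* **FTE time is excluded from the predictor set** of the other conditionals
  because it is structurally absent for released trainees; its own model is
  fitted on non-released records only, and cells whose current ARCP draw is
  TRUE are set structurally absent each cycle.
* **LTFT/OOP are imputed as indicators** (matching the imputed-variable
  list); records imputed positive receive durations hot-decked from the
  observed positive-duration distribution. Durations only decorate the
  completed datasets — outcomes are computed from the imputed FTE time
  directly.
* **Restriction of range** is handled purely by model extrapolation from the
  always-observed predictors under the missing-at-random assumption; no
  truncation correction is added.
* Per-cycle means of the imputed cells are returned as convergence traces.

Pooling (`pool_scalar()`) is deliberately minimal — arithmetic mean, SD
across imputations, empirical percentiles. Counts, not model coefficients,
are pooled, so no Rubin total-variance combination is needed.

## The synthetic-data generator

The confidential linked dataset is not deposited, so `generate_cohort()`
produces cohorts with the structure the analysis assumes, plus a complete
truth table that downstream estimates can be validated against.

A latent aptitude `u ~ N(0, 1)` drives everything that should correlate:
each Stage 2 test is `250 + 40 * (0.55 u + sqrt(1 - 0.55^2) e)` points, the
Stage 3 total analogous with loading 0.6, Stage 3 competency and release
from training are logistic in `u`, and the FTE extension beyond the minimum
36 months is a two-part model — on-time with probability
`plogis(-0.0113 + 0.5 u)`, otherwise `Gamma(0.8, scale 19.82 * exp(-0.3 u))`
months. Withdrawal (12%), offer decline (9%), LTFT (25%, mean 12 months)
and OOP (10%, mean 6 months) are independent of `u` by default: nothing is
known about their aptitude dependence, and slopes are exposed as parameters
without claiming empirical support. Demographics (gender, ethnicity, PMQ
country) are generated with zero outcome effects for the same reason.

Numbers that define the stated world, chosen once:

* **Cohort shape**: 6341 applications/year for 4 years, 18% in Round 2,
  ~3000 appointments/year — the aggregate accounting of the real 2011–14
  cohort.
* **Score scale**: mean 250, SD 40 per test, placing the per-test cut of
  181 about 1.7 SD below the mean. The published aggregates imply the cut
  plus the competency requirement cap fills near 3000/year out of ~5100
  fillable; with the competency intercept at 0.85 the synthetic cap lands
  near 3200/year — above the last fillable published target (3000) and
  safely below the first unfillable one (3500).
* **Outcome calibration** (prescribed): the on-time intercept and delay
  scale were solved numerically (quadrature + `optim`, frozen before any
  testing) so that randomly selected entrants register at 52% within 3
  years FTE and 79% within 5 — the published random-selection rates. The
  implied release-from-training rate is 11.7%.

`apply_historical_selection()` then imposes the observation pattern of a
2015-style process: Stage 3 score, competency and the withdrawal flag are
observed only above the cut; offers cascade down the Stage 2 + Stage 3
ranking until the yearly appointment target accepts, so accept/decline is
observed exactly for those offered; training outcomes are observed only for
appointed trainees. Masking depends only on always-observed scores, so the
missingness is missing-at-random *by construction* — a green imputation
test therefore establishes correctness under MAR, not robustness to
not-missing-at-random selection.

Features of real data the generator does **not** emulate: administrative
censoring of late starters (appointed records have complete follow-up, so
that "appointed implies fully observed" holds exactly); repeat applications
by the same doctor; regional deaneries and their differing fill rates;
year-on-year applicant decline; demographic outcome gaps. Registration
dates are stored at month resolution, so observed FTE times match the
continuous truth table only to about half a month.

## Selection processes

All four processes draw on pools that exclude withdrawals and declined
offers. Random selection samples the Round 1 pool uniformly; Stage 2 /
Stage 3 rankings take the top of the Round 1 pool with no cut; the 2015
process requires 181+ on each Stage 2 test and Stage 3 competency, filling
Round 1 before Round 2 (the source does not say whether rounds were filled
sequentially or simultaneously; sequential is implemented). Within the
qualifying pool the 2015 process ranks by Stage 2 + Stage 3 totals — the
least arbitrary choice where the source states only the criteria — with a
`rank_by = "stage2"` alternative. Ties are broken by a seeded uniform draw,
which makes ranked selections reproducible and nested across targets.
Annual targets are applied per application year independently; a
pooled-years mode exists for small cohorts.

## Numerical choices and degenerate inputs

Continuous predictors are standardised inside the design matrix so logistic
coefficients are O(1); predictor columns constant on the fitting rows (e.g.
`offer_accepted` among records with observed training outcomes) are dropped
per fit. Reported percentages round half-up to integers, matching how such
results are conventionally printed; raw values stay in the tables. Empty
cohorts, empty pools, zero targets, all-withdrawn pools and unreachable
appointment targets all have defined behaviour (empty results, warnings, or
named errors) exercised in the test suite. A variable that is 100% missing
has no donors and is a configuration error, not a silent guess.

## Known limitations

* The headline parameter-recovery check (acceptance 3a) measures the bias
  of the pooled 5-year count for a fixed top-2000 selection against the
  truth table over five seeds. The bound — twice the SD of the pooled
  counts across seeds — is met, but a small positive bias (computed by the
  test, about +0.9% of the count) remains. Its source is structural: the
  true score-to-delay relationship is convex, so a linear conditional model
  matched by PMM slightly underestimates delays when extrapolating below
  the observed score support. This is the cost of the stated
  restriction-of-range strategy, shared by any linear FCS engine; it is
  documented rather than tuned away.
* The SD across imputations understates total uncertainty for the random
  process, where selection randomness (fresh draws per imputation) mixes
  with imputation noise.
* Extension lengths are not modelled — a registrant at 39 FTE months and
  one at 61 count identically as extensions.
* No costing of extensions or released trainees is attempted.
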