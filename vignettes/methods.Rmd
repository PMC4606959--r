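---
title: "Joint estimation of congenital heart disease birth prevalence and excess mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint estimation of congenital heart disease birth prevalence and excess mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The estimation problem

Congenital heart disease (CHD) is present from birth, is not acquired later,
and is essentially never cured; what changes over a patient's life is the
risk of dying from it. Two routinely collected data streams see different
parts of this process: population surveys measure the *prevalence* of
(recalled, doctor-diagnosed) CHD among children, and cause-of-death
certificates measure the *cause-specific mortality rate* (CSMR) at every
age. Neither stream alone identifies how many adults currently live with
CHD — survey questions are asked only about children, and death counts
confound how many people have the condition with how lethal it is.

`chdprev` couples the two streams through a one-compartment model. Let
\(p(a,t)\) be the proportion of the population of age \(a\) in calendar
year \(t\) living with the condition, \(p(0,t)\) the *birth prevalence*,
and \(\chi(a,t)\) the *excess-mortality hazard* (per person-year) among
prevalent cases. Along each birth cohort (the characteristic line
\(a = t - c\) for birth year \(c\)),

\[ \frac{dp}{da} = -\chi(a, c + a)\, p, \qquad p(0) = p(0, c). \]

The model assumes no incidence after birth, no remission, and no protective
effect. With prevalence near 3 per 1,000 the logistic saturation term
\((1-p)\) changes \(p\) by under 0.2%, so the linearized equation is the
default (`solve_cohort(saturation = TRUE)` provides the exact logistic
variant). Survey observations are compared with population-weighted means
of \(p\) over their age interval; CSMR observations with means of
\(p \cdot \chi\), i.e. every condition-coded death is treated as an excess
death among prevalent cases.

## Numerical solution along characteristics

Surfaces live on a grid of single-year ages \(0\ldots A\) and calendar
years. The solver steps each cohort with exact per-step survival factors
\(\exp(-\bar\chi)\), where \(\bar\chi\) is the geometric mean of the node
hazards at the two step endpoints (the midpoint on the log scale). This is
exact for hazards log-linear within a step, keeps \(p\) positive and
non-increasing unconditionally, and reproduces \(p_0 e^{-\chi a}\) exactly
for constant hazards. Cohorts that are already alive at the left edge of
the grid are handled by the boundary rule that birth prevalence and hazards
are constant across cohorts before the first data year, so their entry
state is the first-year age profile. The same rule applied *forward* is the
projection assumption: beyond the last data year, cohorts inherit the
final-year birth prevalence and the hazard repeats its final-year age
profile.

## Data model

Observed rates are modelled on the log scale with an offset:
\(\log(y + \delta)\) is Gaussian. The offset keeps the many exact-zero
cells of a rare condition at finite density; zero observations are
retained, never dropped. Two refinements matter in the sparse-count regime
(survey cells here have ~350 respondents and about one expected positive):

* the delta-method sampling variance is evaluated at the *predicted* rate,
  \(V = q/(n(q+\delta)^2)\) for prediction \(q\) and effective sample size
  \(n\). Evaluating it at the observed value would weight cells by their
  observed counts, which discards zeros and selects upward fluctuations —
  in simulation that mis-weighting biased recovered birth prevalence
  upward by more than 50%;
* the Gaussian centre carries the second-order Jensen correction
  \(m = \log(q+\delta) - V/2\), because the mean of a log is below the log
  of a mean.

The default offset is one count at the measure's median effective sample
size, \(\delta = 1/\tilde n\). Tabulating the exact Poisson moments of
\(\log(c + \delta n)\) against this Gaussian model shows a residual
centring error of about +0.2% at one expected event per cell and within
1–2% from half an event upward, while the model variance matches the exact
variance to three digits; smaller offsets leave the model badly centred
once zero cells appear. A global dispersion term (SD 0.1 on the log scale,
added in quadrature) absorbs residual misfit in cells whose counts are
large enough that sampling noise is negligible. The exported
`loglik_offset_lognormal()` defaults to the plain symmetric textbook form;
the fit and the bootstrap use the corrected form explicitly
(`moment_correct = TRUE`).

## Priors and fitting

The log-hazard surface is penalized by second-order finite differences in
three directions — age (within each year), cohort (along characteristics),
and the mixed age-by-year cross difference — each divided by
\(2\sigma^2\) with \(\sigma = 1\) on the log scale. The penalty vanishes
exactly for log-affine surfaces, so it shrinks toward locally log-linear
behaviour without forcing a level. "Cross-smoothing" is implemented as the
mixed second difference, which vanishes for any additively separable log
surface; this is an interpretation, as the term has no canonical
definition. The smoothing scale is treated as the scale of second
differences of *logs*, which keeps the prior free of the rates' units.

Birth prevalence is constrained constant over time by default (the model
names a time-specific \(p(0,t)\), but the constant-rate assumption is the
documented default; `constant_birth_prevalence = FALSE` frees it on the
year-knot basis with its own second-difference penalty — the tension
between the two conventions is deliberately left visible rather than
resolved). Survey rows for age 0 are excluded by default to avoid
age-differential response bias; the rows are still generated so the
exclusion is testable.

Both surfaces are log-parameterized on knots (ages 0, 1, 5, then every 5
years; calendar years every 5 years) with bilinear interpolation, keeping
the optimization at roughly 160 parameters per sex. Fitting maximizes
penalized likelihood with L-BFGS-B (bounds on the log scale, projected
gradient tolerance \(10^{-8}\), explicit non-convergence flag) using an
exact analytic gradient obtained by reverse accumulation through the
cohort recursion; the gradient is verified against central finite
differences in the test suite. The start is deterministic: birth prevalence
at the crude survey prevalence and the hazard at the empirical age profile
of crude CSMR divided by that prevalence, flat in time. The age profile in
the start is not cosmetic: an age-flat start places the steep infant cells
in a spurious basin where predictions collapse below the data and the
prediction-based variance removes the restoring pull.

Sexes are fitted separately throughout.

## Uncertainty

Uncertainty intervals are parametric bootstrap: new data are drawn from the
fitted data model at the point predictions (same per-observation variance),
the model is refit warm-started from the point estimate, and the 2.5th and
97.5th percentiles across replicates form the 95% interval. Pseudo-data
are passed to the refit on the model's log scale without truncation at
zero: censoring draws below \(-\delta\) at zero shifts the refit data
upward and visibly biases the intervals. Derived quantities (prevalent
counts, band prevalences) are recomputed per replicate and percentiled on
the derived scale, never by transforming surface intervals. Replicates
whose refit fails to converge are dropped with a log message; more than
20% dropped is a hard error. The production default is 1,000 replicates;
the simulation studies in this package use 200 (coverage) or fewer (unit
tests).

## The synthetic scenario

The generator emulates the three real input streams with known truth:

* **Birth prevalence** 3.29 (males) / 3.23 (females) per 1,000, constant
  over time.
* **Hazard** \(\chi(a,t) = (0.52\,e^{-a/1.5} + 0.004)\,
  e^{-0.0277\,(t-1968)}\): an infant peak declining roughly threefold over
  four decades and a near-flat adult floor. At these values the implied
  infant CSMR runs from ~170 to ~53 per 100,000 person-years across the
  1968–2010 window and roughly half of prevalent infants died of the
  condition in 1968 versus about one in six by 2010, matching the regime
  the model is meant for. The optional `decline_until` year levels the
  hazard off earlier (observed mortality-rate series do flatten late in
  the window).
* **Population**: births of 1.7M per sex per year growing at 0.7%/yr,
  thinned by a background survival curve with an infant component and a
  Gompertz old-age tail. This is deterministic; denominators carry no
  sampling noise.
* **Deaths**: Poisson with mean \(N \cdot p \cdot \chi\) per age/sex/year
  cell over 1968–2010.
* **Survey**: Binomial positives out of 350 respondents per age/sex/year
  cell, ages 0–17, 1997–2011 (about 189,000 respondent records in total,
  the scale of the real survey series; real per-cell sample sizes are not
  published, so this default is flagged as arbitrary).

Each simulated table draws from its own seeded stream keyed by
`(seed, table name)`, so generating one table never perturbs another and
identical seeds give byte-identical tables.

What the generator does *not* emulate: multistage survey design, weights
and household non-response; certificate-level cause miscoding and ICD
revision breaks; migration; sub-annual infant ages (age 0 stands in for
0–51 weeks). Passing the recovery and coverage suites therefore shows the
estimator is consistent and calibrated *when the data model is broadly
right*, not that the real data meet it.

## Problem sizes used by the simulation studies

The recovery study (20 seeded replicates, both sexes) runs on the full
default scenario: ages 0–70, years 1968–2011, ~3,300 observations and 161
parameters per sex. The bootstrap coverage study (50 truths x 200
replicates) needs about ten thousand refits, so it runs on a reduced
scenario chosen for turnaround: death window 1991–2010, maximum age 66,
coarser knots (ages 0, 1, 5, 10, then every 10 years; calendar years every
10), males only. The coverage property being checked is scale-free; the
reduced scenario just keeps the refits cheap.

The plateau check uses truth surfaces directly (no fitting): with rates
stationary from 1990 on and a stationary population, the 20–64 band's
prevalence per capita converges as pre-stabilization cohorts wash out of
the band. Convergence of this band is complete only once its youngest
member was born after stabilization — about 64 years — so the check is run
on a scenario whose hazard stops declining 20 years before the window end;
under the default scenario (decline through 2010) the same statistic at
+40 years is still dominated by cohort replacement and the plateau
arrives correspondingly later.

## Degenerate inputs and edge rules

Zero-valued observations are retained via the offset. Zero birth
prevalence propagates exact zeros along the cohort. A hazard of zero is
allowed in `solve_cohort` (identity cohort) but hazard *surfaces* must be
strictly positive. Observation intervals outside the grid, missing
population cells, and sexes lacking either data stream are hard errors
with named cells rather than silent drops. Records with an empty cause
list are excluded with a warning and counted; records missing age or sex
are dropped with a logged count. The adult band is ages 20–64 inclusive
(the upper bound is configurable, as published usage varies between 20–64
and 20–65).

## Known limitations

* The ICD code map is an editable approximation of the unpublished
  cause-list table (include 745.0–747.49 / Q20–Q26, exclude 747.5–747.9 /
  Q27–Q28); revision-bridging comparability ratios are out of scope.
* The offset log-normal remains an approximation to the count likelihoods;
  below about half an expected event per cell its centring error grows,
  which is why the offset is calibrated to the median cell and not per
  observation.
* Percentile intervals do not correct estimator bias (no BCa), and
  denominators and classification are treated as known.
* Severity stratification, covariates, remission and adult-onset incidence
  are intentionally outside the model.
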