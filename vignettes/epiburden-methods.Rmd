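---
title: "Methods: the illness-death consistency model and DALY pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the illness-death consistency model and DALY pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Estimating the disability-adjusted life-year (DALY) burden of a chronic
condition from a surveillance site requires three ingredients that raw
stratum tables do not supply directly: an internally consistent set of
epidemiological rates (observed prevalence, incidence and mortality need
not agree with one another under any single disease process), a morbidity
component (years lived with disability, YLD), and a mortality component
(years of life lost, YLL) valued against a standard life table. `epiburden`
implements that chain for stratified (sex x age-band) count data of the
kind a health-and-demographic surveillance system (HDSS) produces, with
convulsive epilepsy in a rural South African site as the packaged worked
example.

## The illness-death model

The disease process is the classic three-state illness-death model with
remission. Writing `W(a)` for the fraction of a birth cohort alive and
disease-free at age `a` and `C(a)` for the fraction alive with disease,

    dW/da = -(i + m) W + r C
    dC/da =  i W - (r + m + f) C

with four hazards, all in events per person-year and all assumed constant
within an age band:

| hazard | meaning | typical magnitude here |
|---|---|---|
| `i` | incidence (well to diseased) | 1--3 per 10,000 py |
| `r` | remission (diseased to well) | 0--0.3 per py |
| `f` | excess (cause-specific) mortality of cases | 0--0.1 per py |
| `m` | background all-cause mortality | 1--45 per 1,000 py |

Derived quantities: age-specific prevalence `p(a) = C/(W+C)`; expected
remaining duration of disease `D(a)`, the mean sojourn in `C` under exit
hazard `r+m+f` over the remaining ages; and the standardized mortality
ratio `SMR = (m+f)/m`. When `f = 0` the SMR is exactly 1, and when
`r = f = 0` the model has the closed form `p(a) = 1 - exp(-i a)` — both
are pinned by tests, along with the constant-hazard sojourn
`D = 1/(r+m+f)`.

`idm_solve()` integrates the system by fixed-step classical Runge-Kutta on
a 0.1-year grid from age 0 to 100 (the open-ended 50+ band is truncated at
the life table's terminal age). Because hazards are band-constant the
system is linear with piecewise-constant coefficients, so the RK4 update
is a per-band 2x2 step matrix applied along the grid; this makes runs fast
and bit-reproducible, and inside the fitter whole-band propagation reduces
to a matrix power. The scheme is cross-checked in the test suite against
an independent adaptive integrator (`deSolve::lsoda`) and against the
closed forms at 1e-4 relative tolerance. Duration uses the exact backward
recursion for piecewise-constant exit hazards rather than quadrature, so
it is stable for any hazard magnitude. Duration at an age with no disease
and no incidence is reported as zero (undefined-as-zero convention).

### Consistency fitting

`idm_fit()` accepts band-level observations of at least three of
prevalence, incidence, remission and cause-specific mortality (plus
background mortality `m`, which is held fixed at its observed value) and
finds the hazards whose forward solution reproduces them, by weighted
least squares. Weights are inverse-variance from the observations'
standard errors — Poisson errors are derived automatically when the input
is a stratum count table; a scale-normalised fallback is used when no
errors are available. The model-implied observations are: prevalence at
the band midpoint, incidence per total person-year `i (1 - p)`, remission
`r`, and cause-specific population mortality `f p`.

Bands are fitted youngest-first ("forward conditional" block WLS): each
band's `(i, r, f)` is optimised with `nlminb` under box constraints
(`>= 0`, with generous upper caps of 1, 10 and 10 per person-year), and
the state vector is carried across the band boundary. With three
observations and three unknowns per band the minimiser interpolates
noise-free data exactly, which is why the round-trip test demands recovery
within 1% — in practice it achieves ~1e-8. When remission is not observed,
`r` is identified only through the prevalence dynamics and is the noisiest
component; incidence remains well determined. A sex with no observed
disease at all returns zero hazards flagged `"unidentified"` rather than
silently. Non-convergence (an optimiser iteration cap) is likewise
flagged, never hidden. When cause-specific deaths are available,
background mortality is computed as (all-cause minus cause-specific
deaths) per person-year so the excess hazard is not double counted.

Observed stratum-level all-ages rows, where present in input tables, are
ignored by the fitter (they are linear combinations of the bands); the
`summary()` method recomputes all-ages rows by band-width weighting.

### Uncertainty, stage one (Monte Carlo)

`propagate_uncertainty()` perturbs every observed rate with an independent
normal draw truncated at zero (rates cannot be negative), refits, and
reports 2.5th/97.5th percentiles over the iterations (default 1,000). A
zero standard error pins an input exactly, so the no-noise interval
degenerates to the point estimate; a fixed seed makes the intervals
reproducible. This fit-stage uncertainty and the burden-stage bootstrap
below are deliberately separate stages — they are not nested into a single
combined interval by default, since the appropriate nesting depends on
whether the consistency inputs and the burden inputs share sampling error.

## Burden arithmetic

* Prevalence-based YLD (per annum): `population x prevalence x DW`.
* Incidence-based YLD: `population x incidence x duration x DW`.
* YLL: cause-specific deaths per year, each valued at the standard
  remaining life expectancy at the age of death. Stratum-level deaths are
  assigned a representative age per band (`midpoint` by default,
  configurable to `lower`/`upper`), since individual death ages are not
  available in stratum tables.
* `DALY = YLL + YLD`, exactly, in every cell and every bootstrap draw.

No age weighting and no discounting are applied anywhere; there is no
discount parameter that can influence results. All computation is kept in
full precision; rounding to one decimal (tables) or integers (headline
percentages) is presentation-layer only. Both YLD approaches use a single
reference population (the baseline year of the follow-up), which is what
makes them comparable; in a stationary population where
`prevalence = incidence x duration` they agree to machine precision, a
property the test suite asserts, together with the person-time-weighted
stationarity identity `P = i D (1 - P)` of the forward solution.

The method comparison reports
`(YLD_inc - YLD_prev) / YLD_inc x 100` and the corresponding DALY
difference with YLL common to both methods. It is computed from all-ages
aggregate rates; the per-band prevalence pathway is a separate reporting
mode. The packaged fixture tables keep both pathways, which are not
mutually consistent in the source (their all-ages YLDs differ); fixtures
are labelled by the table they mirror and the discrepancy is documented
rather than reconciled.

## Disability-weight sensitivity

The weight enters both YLD formulas multiplicatively, so the one-way scan
is exact rescaling: `YLD(dw) = YLD_ref x dw / dw_ref`; DALY changes follow
with YLL held fixed. The default set is the GBD 2010 epilepsy severity
range — 0.072 (treated, seizure-free), 0.319 (treated, recent seizures),
0.420 (untreated), 0.657 (severe) — around the sub-Saharan-Africa mean
reference 0.346. Uncertainty bounds of the reference YLD are rescaled by
the same factor; this is exact for a linear statistic and is documented as
an approximation to re-running the bootstrap per weight.

## Bootstrap uncertainty, stage two

`bootstrap_interval()` wraps the `boot` package. The default resampling
unit redraws every stratum event count as `Poisson(observed)` — the
natural model for rare events against person-time denominators — with
zero-truncated normal draws of rates (`"parametric"`) and ordinary row
resampling of case lists (`"cases"`) as alternatives. Intervals are
percentile (2.5/97.5); the percentile method was chosen over BCa as the
simplest method consistent with mildly asymmetric count intervals.
Replicates on which the statistic fails are dropped and counted, with more
than 5% failures an error. On synthetic cohorts with known truth the 95%
YLD intervals attain 93--97% empirical coverage (500 replicates, asserted
in the acceptance tests).

## The synthetic cohort generator

`generate_cohort()` emulates an HDSS cohort: two sexes by six age bands
(0--5, 6--12, 13--18, 19--28, 29--49, 50+), stratum populations and four
years of follow-up at the packaged site's scale (~80,000 residents), with
expected counts taken from the forward solution (baseline prevalent cases
from midpoint prevalence; incident cases, cause-specific and background
deaths from the band hazards applied to person-time) and realised counts
drawn Poisson. The default truth (`agincourt_cohort_spec()`) mirrors the
packaged site's published rate structure. A multiplicative-noise mode
(independent truncated-normal factors, default sd 0.05) supports
observation-error studies, and an optional uniform person-year thinning
stands in for loss to follow-up (default off — the source reports no
rate). Person-years are deterministic `population x years`; mortality
erosion of person-time within strata is second-order at these rates and
is not simulated.

What the generator does *not* emulate: individual event histories,
migration, village-level clustering, secular trends in incidence, or
measurement error in case ascertainment. Passing recovery and coverage
tests therefore demonstrates statistical correctness of the pipeline
under its own sampling assumptions, not robustness to those real-data
features.

### Validation study sizes

The replicate studies are sized to be decisive yet quick: 100 replicates
for parameter recovery under 5% multiplicative observation noise (median
relative incidence error must stay below 10%; pure Poisson counting noise
at this site's scale — roughly 55 incident cases over four years — is a
~40% CV problem per band and is not a meaningful recovery target), 500
replicates at 1,000 bootstrap iterations for interval coverage, and 100
replicates for the end-to-end burden error study. For the end-to-end
study the a priori delta-method analysis sets the bar: ~16 expected
cause-specific deaths give the YLL component ~25% sampling CV, hence a
DALY CV near 18% and an expected median |relative error| around 12%; the
test asserts the corresponding bounds (median < 20%, mean bias < 10%)
rather than a tighter figure the counting statistics cannot support.

## Numerical and design choices

* Grid: 0.1-year steps; band boundaries are integers so bands align with
  the grid, and band midpoints are grid-snapped.
* Open-ended band: truncated at the life table's last age (100). The
  closed-form solver checks use a longer horizon (300 years) so that
  truncation error, which decays like `exp(-lambda x horizon)`, is
  negligible against the 1e-4 tolerance.
* The packaged standard life table is the GBD 2010 standard reference
  table (86.02 years at birth, both sexes); it is swappable via
  `life_table: {path: ...}` and only its value at birth is load-bearing
  for the packaged results.
* Duration intervals in the fixture schedule: the female 0--5 entry's
  interval is unparseable in the source and is stored as missing.
* The fixture schedule's "standardized mortality rate" column is treated
  as a ratio (values like 7.7 and 20.2 against per-1,000 background rates
  only make sense as ratios).
* Seeds: every stochastic entry point takes a seed and defaults to
  20151223; pipelines record the seed and a config hash in every output.
* Table-2-style outputs can be smoothed onto a continuous age axis with
  `smooth_schedule()` (piecewise-linear, window-3 moving average, or
  natural cubic spline through band midpoints).

## Limitations

* The consistency fit is block-sequential: observations in older bands do
  not revise hazards already fitted in younger bands. This is exact for
  noise-free data and cheap under replication, but a joint fit could pool
  slightly more information under noise.
* Remission is weakly identified when only prevalence, incidence and
  mortality are observed, particularly in the youngest band where
  prevalence is still nearly linear in age.
* Stratum-level YLL depends on the band-age convention; with individual
  death ages unavailable, midpoint assignment is the standard
  approximation and the convention is configurable.
* The packaged burden fixtures reproduce a published analysis whose
  internal tables disagree at the 0.1-year level due to rounding in the
  source; totals computed from the printed components can differ from the
  printed totals in the last decimal.
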