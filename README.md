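# epiburden

Burden-of-disease estimation from stratified surveillance data, built
around an illness-death consistency model. The package is aimed at
epidemiologists estimating the disability-adjusted life-year (DALY)
burden of a chronic condition — here, convulsive epilepsy in a rural
health-and-demographic surveillance site — from sex- and age-band-level
counts of cases, deaths and person-years.

## What it computes

**The consistency engine.** Observed prevalence, incidence and mortality
from a field site rarely describe a single coherent disease process.
`idm_fit()` fits the three-state illness-death model

    dW/da = -(i + m) W + r C
    dC/da =  i W - (r + m + f) C

(W disease-free, C diseased; hazards per person-year: incidence *i*,
remission *r*, excess cause-specific mortality *f*, background mortality
*m*, all band-constant) so that the forward solution reproduces the
observations by weighted least squares. The fitted object reports the
mutually consistent incidence, prevalence, remission, duration and
standardized-mortality-ratio schedules, with `print`, `summary`, `coef`,
`predict`, `residuals`, `plot` and `simulate` methods.

**Burden arithmetic.**

* years lived with disability, prevalence-based: `YLD = N x prevalence x DW`
* years lived with disability, incidence-based: `YLD = N x incidence x duration x DW`
* years of life lost: deaths x standard remaining life expectancy at the
  age of death (GBD 2010 standard life table, e(0) = 86.02 years, no age
  weighting, no discounting)
* `DALY = YLL + YLD`, with absolute and per-1,000 reporting by sex and
  age band

plus one-way disability-weight sensitivity analysis (`dw_scan()`),
Monte-Carlo propagation of input uncertainty through the fit
(`propagate_uncertainty()`), bootstrap 95% uncertainty intervals for any
burden statistic (`bootstrap_interval()`, Poisson resampling of stratum
counts by default), a synthetic HDSS cohort generator with known truth
(`generate_cohort()`), and an end-to-end pipeline (`run_pipeline()`)
that writes the full table bundle plus a machine-readable summary.
A thin command-line front end ships in `inst/cli/epiburden.R`.

## Worked example

The packaged fixtures carry the published surveillance aggregates for a
site of 39,313 males and 42,443 females. Computing both YLD approaches at
the reference disability weight 0.346:

```r
library(epiburden)

yld_p <- yld_prevalence(c(39313, 42443), c(2.6, 2.4) / 1000, 0.346)
yld_i <- yld_incidence(c(39313, 42443), c(19.4, 17.2) / 1e5,
                       c(21.5, 19.7), 0.346)
round(yld_p, 1)
#> [1] 35.4 35.2
round(yld_i, 1)
#> [1] 56.7 49.8
```

So males carry 35.4 prevalence-based YLD per annum against 56.7
incidence-based (females 35.2 vs 49.8): the prevalence approach yields
38% and 29% less YLD, and with years of life lost included, 10% fewer
DALYs for either sex —

```r
cmp <- compare_methods(yld_p, yld_i, yll = c(151.6, 95.7))
cmp$pct_diff_yld_int
#> [1] 38 29
cmp$pct_diff_daly_int
#> [1] 10 10
```

Varying the disability weight across the GBD 2010 epilepsy severity
states rescales the both-sex reference YLD (84.8 years at DW 0.346, YLL
247.4) exactly:

```r
dw_scan(84.8, 0.346, yll = 247.4)
#>                    state    dw   yld pct_change_yld  daly pct_change_daly_int
#>                reference 0.346  84.8            0.0 332.2                   0
#>     treated_seizure_free 0.072  17.6          -79.2 265.0                 -20
#>  treated_recent_seizures 0.319  78.2           -7.8 325.6                  -2
#>                untreated 0.420 102.9           21.4 350.3                   5
#>                   severe 0.657 161.0           89.9 408.4                  23
```

That is: pricing every case as treated-and-seizure-free cuts total DALYs
by 20%, while severe epilepsy raises them by 23% — the choice of disease
model moves the headline burden by more than a fifth in either direction.

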