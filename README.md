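# apcmort

Age-period-cohort (APC) modelling of maternal mortality with restricted
cubic splines, plus the supporting machinery a maternal-mortality analysis
needs: Lexis tabulation of record-level deaths against live-birth
denominators, crude maternal mortality ratios (MMR, deaths per 100,000 live
births), equal-variance two-sample t tests comparing mean annual deaths
between population groups, and a synthetic-data generator with known truth
for validating the whole pipeline.

The intended user is an epidemiologist or health-policy analyst asking how
maternal mortality decomposes along the three time axes — the mother's age
at death, the calendar period of death, and her birth cohort — when the
data are individual death records (with social covariates such as schooling,
marginalization level, medical care at delivery and health-system
affiliation) and births tabulated by maternal age and year.

## The model

Deaths are tabulated on a one-year Lexis grid: cell *(i, j)* holds the death
count *D<sub>ij</sub>* and live-birth exposure *N<sub>ij</sub>*, with birth
cohort *k = j − i*. Counts are modelled as Poisson with a log link and
offset,

&nbsp;&nbsp;&nbsp;&nbsp;log E(D<sub>ijk</sub>) = log N<sub>ijk</sub> + μ + α(i) + β(j) + γ(k),

where α, β, γ are restricted cubic spline functions (linear beyond the
boundary knots, knots at exposure-weighted quantiles). Because
*k = j − i*, the three linear trends are not jointly identifiable; the
package pins down the classic convention explicitly:

* **age block** — intercept + full spline of age (level and age slope live
  here); α is reported as the age-specific rate per 100,000 live births at
  the reference cohort and trend-free period;
* **period block** — spline curvature of period, detrended (orthogonal to
  level and trend), reported as a rate ratio whose log averages 0 over the
  observed years;
* **cohort block** — a single *drift* column carrying the secular
  log-linear trend per cohort year, plus detrended spline curvature
  anchored so that the cohort rate ratio is exactly 1 at the reference
  cohort (1980 by default).

The model is fit by iteratively reweighted least squares (IRLS) with
step-halving; confidence bands are delta-method intervals on the log scale.

## Worked example

```r
library(apcmort)

sim <- simulate_lexis(truth = true_effects(), exposure = exposure_uniform(1e5),
                      age_range = c(10, 54), period_range = c(2002, 2014),
                      seed = 1, records = TRUE)
fit <- apc_fit(sim$table, apc_spec())
fit
#> Age-period-cohort Poisson rate model
#>   585 cells, 15 parameters, 6 IRLS iterations
#>   log-likelihood -2070.7370, deviance 588.9452, AIC 4171.47, BIC 4237.05
#>   cohort drift -0.0310 per year (se 0.0017, z -18.47)
```

The generator's truth has a U-shaped age effect (minimum at age 27) and a
declining cohort trend of −0.0304 per birth year; the fit recovers both.
The age curve is the fitted mortality rate per 100,000 live births:

```r
as.data.frame(age_effect(fit, grid = c(13, 27, 42)))
#>    x estimate    lower    upper
#> 1 13 65.26666 59.49452 71.59881
#> 2 27 37.93111 36.68058 39.22427
#> 3 42 66.28281 61.65484 71.25817
```

— elevated risk for very young and older mothers relative to the minimum
near age 27. The cohort curve is a rate ratio anchored at the 1980
reference cohort (women born before 1980 carry RR > 1, later cohorts
RR < 1):

```r
as.data.frame(cohort_effect(fit, grid = c(1960, 1980, 2000)))
#>      x  estimate     lower     upper
#> 1 1960 1.8245107 1.6861395 1.9742372
#> 2 1980 1.0000000 1.0000000 1.0000000
#> 3 2000 0.5215509 0.4663077 0.5833387

drift(fit)$estimate
#> -0.0310   # 95% CI (-0.0342, -0.0277); truth -0.0304
```

Group comparisons on the record stream use the pooled two-sample t test on
the 13 annual death counts per category, reporting the two-sided and both
one-sided p-values:

```r
compare_groups(sim$records, "medical_care", list("no", "yes"), 2002:2014)
#> Two-sample equal-variance t test
#>   means 1570.3846 vs 1564.6923 (n = 13, 13)
#>   difference 5.6923 (se 74.5962), t = 0.0763, df = 24
#>   Pr(|T|>|t|) = 0.9398  Pr(T>t) = 0.4699  Pr(T<t) = 0.5301
#>   95% CI for difference: (-148.2666, 159.6512)
```

(the simulator assigns covariate labels uniformly, so no real difference is
expected here). Working from published summary rows instead,
`t_from_difference(2.008, 0.497)` returns t = 4.040.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates a full Lexis world with the default truth, tabulates it, fits
the APC model, writes the three effect curves and a group comparison, runs
a compact parameter-recovery pass, and writes its results JSON to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Package layout

* `R/lexis.R` — reading records/births, Lexis tabulation, crude MMR
* `R/rcs.R` — restricted cubic spline bases; detrending and reference
  anchoring (the identifiability transformations)
* `R/apc.R` — design assembly, IRLS Poisson fitter, effect curves, drift
* `R/grouptests.R` — pooled two-sample t machinery
* `R/synthetic.R` — truth specification, exposure models, simulators,
  parameter-recovery studies
* `R/pipeline.R` — end-to-end pipeline with stamped, machine-readable
  artifacts
* `vignettes/apc-maternal-mortality.Rmd` — the methods vignette: model,
  identification scheme, defaults and their rationale, limitations
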