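---
title: "Age-period-cohort analysis of maternal mortality: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age-period-cohort analysis of maternal mortality: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcmort)
```

## The problem

Maternal mortality — deaths from pregnancy-related causes, conventionally
reported as the maternal mortality ratio (MMR): deaths per 100,000 live
births — varies along three entangled time axes: the mother's age at death,
the calendar period of death, and her birth cohort. Separating these matters
for policy: an age effect points at clinical risk groups (teenage and older
mothers), a period effect at system-wide events (programmes, crises), and a
cohort effect at slowly improving social determinants experienced by
successive generations of women. `apcmort` implements this decomposition
for record-level death data with live-birth denominators, together with the
simpler group comparisons (schooling, marginalization, access to medical
care, health-system affiliation) that motivate the social-determinants
reading of the results.

## The model

Deaths are tabulated on a one-year Lexis grid. For cell $(i, j)$ (age $i$,
year $j$, cohort $k = j - i$) with live-birth exposure $N_{ijk}$, the death
count is modelled as Poisson,

$$
D_{ijk} \sim \mathrm{Poisson}(\lambda_{ijk} N_{ijk}), \qquad
\log \lambda_{ijk} = \mu + \alpha(i) + \beta(j) + \gamma(k),
$$

with $\alpha, \beta, \gamma$ restricted cubic splines: piecewise cubics,
continuous through the second derivative at every knot, constrained linear
beyond the boundary knots. Exposure is live births, the MMR convention
(person-years would be the alternative for general mortality; for maternal
mortality the denominator of record is births, and the package keeps that
convention throughout).

### Identification

Because $k = j - i$ exactly, the level and the three linear trends of
$\alpha, \beta, \gamma$ are not jointly identifiable: adding $c_1 + c_2 j$
to the period effect and subtracting the same trend from the age and cohort
effects leaves every fitted rate unchanged. Any APC decomposition is
therefore a *convention*, and the convention must be stated. This package
pins it as follows:

* the intercept and the age slope belong to the **age block** (intercept
  column + full spline basis of age). The age curve is then interpretable
  as the fitted age-specific rate for the reference cohort at the
  trend-free average period — the natural first-order summary;
* the single secular log-linear trend (**drift**) is attributed to
  **cohort**, as one column $k - k_{\mathrm{ref}}$;
* the **period block** contains only spline curvature columns of period,
  detrended: each column is orthogonal (ordinary inner product) to the
  constant and to $j$, so the period effect is a trend-free rate ratio
  whose log averages zero over the observed years;
* the **cohort curvature block** contains spline curvature columns of
  cohort, detrended in $k$ and then anchored (shifted by constants) so all
  columns are exactly zero at the reference cohort. The cohort rate ratio
  is thus exactly 1 at the reference and its slope is carried entirely by
  the drift column.

Detrending the cohort curvature before anchoring is a deliberate choice:
with curvature columns carrying incidental linear components, the "drift"
coefficient would absorb only part of the secular trend and its value would
depend on the knot layout. Detrending makes drift *the* identifiable
log-linear trend, which is what a reader compares across studies. A unit
test verifies the flip side: re-allocating a linear trend between the
period and cohort blocks changes the decomposition but leaves every fitted
cell rate unchanged (to 1e-8), the classic statement of APC
non-identifiability.

The default reference cohort is 1980 — the generation boundary the
maternal-mortality literature on Mexico uses, with women born before 1980
carrying elevated risk — and is configurable in `apc_spec()`.

### Splines and knots

With $k$ knots the restricted cubic basis has $k - 1$ columns (the linear
term plus $k - 2$ restricted truncated-power terms, each scaled by
$1/(t_k - t_1)^2$ for conditioning). Knots sit at equally spaced quantiles
of the exposure-weighted distribution of the variable, boundary knots at
the data extremes; under uniform exposure this reproduces R's type-7
quantiles, so a uniform grid gets equally spaced knots. Knot *counts*
default to 6 per dimension, which yields the 15-column design — 6 age
columns including the intercept, 4 detrended period columns, 1 drift + 4
cohort curvature columns — matching the parameter layout reported in the
applied literature this package's defaults echo. Exact published
coefficients are not reproducible without the original microdata and knot
positions, so the package's validation relies on synthetic data with known
truth instead (below).

### Fitting and uncertainty

The Poisson likelihood is maximized by IRLS with step-halving (deviance is
non-increasing by construction; a property test asserts it). Convergence:
relative deviance change or maximum absolute score below `tol` (default
1e-8), at most `max_iter` (default 100) iterations; the intercept starts at
$\log(\sum D / \sum N)$, everything else at zero. Non-convergence and
diverging coefficient norms (separation) are hard errors, never silent.
The coefficient covariance is the inverse observed Fisher information
$(X^\top W X)^{-1}$; effect bands are pointwise delta-method intervals on
the linear predictor, exponentiated — hence asymmetric on the rate/RR
scale, and exactly degenerate (zero width) at the cohort reference, where
the basis row is identically zero. AIC and BIC are the standard
$-2\ell + 2p$ and $-2\ell + p\log n$. No overdispersion adjustment is
applied by default (pure Poisson); fits store the deviance so a
quasi-Poisson scale can be judged by the user.

### Numerical choices

* Detrending uses two least-squares passes (iterative refinement): with
  calendar years in the thousands a single pass leaves Gram products with
  $\{1, x\}$ of order 1e-7; two passes drive them below 1e-10.
* Evaluating an anchored basis exactly at its reference point returns
  exact zeros (explicit tie-break), so `cohort_effect()` reports RR = 1.0
  there bit-exactly rather than within rounding.
* Duplicate knots from heavily tied data are nudged onto unused data
  values; if that is impossible the construction errors.
* Cells with zero live births are dropped (offset $\log N$ undefined) and
  the drop is reported; rates for empty strata are `NA`, never 0.
* Degenerate tables collapse gracefully: a single-age table reduces the
  age block to the intercept, and — since cohort then equals period minus
  a constant — drops the period block (the two would be collinear), each
  with a warning. Any remaining rank deficiency is an error naming the
  offending block.

## Group comparisons

The social-determinant and health-system contrasts are equal-variance
two-sample t tests on mean annual death counts: the $n = 13$ annual totals
(2002–2014) per category are the observations, giving $df = 24$ per
comparison. The package reports the two-sided and both one-sided p-values
and the difference CI, mirroring how such tables are published.
`t_from_difference()` reproduces a published t statistic from a printed
(difference, standard error) pair; its p-values default to the
large-sample Normal reference (`df = Inf`) because published CI half-widths
in this literature are consistent with a critical value near 1.96 rather
than $t_{24}$ — the effective units of analysis behind printed tables are
not always recoverable, and the choice is exposed as an argument. A Welch
variant is available behind `welch = TRUE`; the pooled test is the default
because the published comparisons assume equal variances. No
multiple-testing correction is applied across the four canonical
comparisons, matching the source analyses; users testing many contrasts
should adjust externally.

## The synthetic world

`true_effects()` states the data-generating truth used throughout the test
suite; its defaults are the package's statement of a realistic
maternal-mortality world, chosen once:

* baseline 38 deaths per 100,000 live births at the age minimum — the
  national MMR level reported for Mexico in international comparisons;
* a quadratic U-shaped log age effect with minimum at age 27 and curvature
  0.0025 per squared year, giving roughly 1.6–1.8× risk at ages 13 and 42
  and ~6× at the extreme of reproductive age — the qualitative pattern of
  elevated adolescent and advanced-age risk;
* cohort drift −0.0304 per birth year (the published secular decline this
  package's defaults echo), zero cohort curvature;
* a flat period effect (optional sinusoidal fluctuation, amplitude 0 by
  default) — "no clear period trend" is the stated world.

Exposure is either uniform (default 100,000 births per cell, convenient
for calibration) or a unimodal fertility schedule (Gaussian kernel peaked
at 27, sd 6 years) spreading 2.2 million annual births — the order of
magnitude of annual births in Mexico — across ages 10–54. Covariate labels
on simulated death records are assigned uniformly unless probabilities are
supplied, so group tests on default synthetic records are null cases.

What a green test establishes: that the tabulation conserves counts, that
the fitter maximizes the stated likelihood, that the identification
conventions hold exactly, and that with Poisson data generated *from the
model family* the truth (drift, age curve shape) is recovered with
near-nominal CI coverage. What it does not establish: robustness to
overdispersion, to cohort effects that violate the smoothness assumption,
to misclassified covariates, or to real registration artifacts
(under-reporting, age heaping) — none of which the generator emulates.

Reproducibility: every generator takes an explicit seed;
`recovery_report()` derives replicate $r$'s stream as `seed + r`, so any
replicate is reproducible in isolation, and fit failures are counted and
reported rather than dropped.

## Limitations

* The APC decomposition is convention-dependent by nature; curves from
  this package are comparable to other software only after aligning the
  identification scheme (where the drift sits, what is detrended, the
  reference cohort).
* One-year Lexis cells without triangle splitting: cohort is the integer
  difference $j - i$, an approximation that blurs adjacent birth years.
* Pure Poisson likelihood; real death counts are often mildly
  overdispersed, which narrows the reported bands.
* The spline tails are linear by construction; extrapolated effects
  outside the observed range are available only behind an explicit
  `extrapolate = TRUE`.
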