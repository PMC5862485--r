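#' True effect surface for the synthetic-data generator
#'
#' Defines the known truth a synthetic Lexis table is generated from. The
#' defaults state the world the model is meant to recover: a U-shaped age
#' effect on the log scale (minimum near age 27, elevated risk for the very
#' young and for older mothers), a declining log-linear cohort trend of
#' -0.0304 per birth year, no cohort curvature, and a flat period effect
#' (optionally a small sinusoidal fluctuation). The baseline is 38 deaths
#' per 100,000 live births at the age-curve minimum for a reference-cohort
#' mother, echoing the national maternal mortality level.
#'
#' @param baseline_rate death rate per live birth at the age minimum,
#'   reference cohort, neutral period (default 38 / 100,000).
#' @param age_min_at age at which the age effect is lowest.
#' @param age_curvature quadratic coefficient of the log age effect per
#'   squared year of distance from `age_min_at`.
#' @param cohort_drift log-linear cohort slope per birth year.
#' @param cohort_curvature function of cohort year added to the log rate
#'   (default identically 0).
#' @param period_amplitude amplitude of an optional sinusoidal period
#'   fluctuation on the log scale (default 0: flat period effect).
#' @param period_cycle cycle length in years of the fluctuation.
#' @param reference_cohort cohort year at which the drift term is zero.
#' @return list of class `true_effects` with component functions
#'   `age_log_rate(age)`, `period_log_rr(year)`, `cohort_log_rr(cohort)`
#'   and the stored parameters.
#' @export
true_effects <- function(baseline_rate = 38 / 1e5,
                         age_min_at = 27,
                         age_curvature = 0.0025,
                         cohort_drift = -0.0304,
                         cohort_curvature = function(k) 0 * k,
                         period_amplitude = 0,
                         period_cycle = 6,
                         reference_cohort = 1980) {
  stopifnot(baseline_rate > 0, age_curvature >= 0, period_cycle > 0)
  structure(list(
    age_log_rate = function(a)
      log(baseline_rate) + age_curvature * (a - age_min_at)^2,
    period_log_rr = function(p)
      period_amplitude * sin(2 * pi * (p - min(p)) / period_cycle),
    cohort_log_rr = function(k)
      cohort_drift * (k - reference_cohort) + cohort_curvature(k),
    baseline_rate = baseline_rate, age_min_at = age_min_at,
    age_curvature = age_curvature, cohort_drift = cohort_drift,
    period_amplitude = period_amplitude, period_cycle = period_cycle,
    reference_cohort = reference_cohort
  ), class = "true_effects")
}

#' Live-birth exposure models
#'
#' `exposure_uniform()` gives every (age, year) cell the same number of
#' births — convenient for calibration studies. `exposure_unimodal()`
#' spreads an annual national total over maternal ages with a smooth
#' unimodal profile peaked near age 27 (Gaussian kernel, sd 6 years),
#' roughly the shape of an observed fertility schedule; the default total
#' of 2.2 million births per year matches the order of magnitude of annual
#' births in Mexico.
#'
#' @param births_per_cell births in every cell (uniform model).
#' @param total_per_year annual national births (unimodal model).
#' @param peak_age,sd_age location and spread of the fertility profile.
#' @return function `f(age, year)` returning expected live births, vectorized.
#' @name exposure_models
#' @export
exposure_uniform <- function(births_per_cell = 1e5) {
  stopifnot(births_per_cell >= 0)
  function(age, year) rep(births_per_cell, length(age))
}

#' @rdname exposure_models
#' @param age_range ages over which the annual total is distributed.
#' @export
exposure_unimodal <- function(total_per_year = 2.2e6, peak_age = 27,
                              sd_age = 6, age_range = c(10, 54)) {
  ages <- seq.int(age_range[1], age_range[2])
  kern <- stats::dnorm(ages, peak_age, sd_age)
  share <- stats::setNames(kern / sum(kern), ages)
  function(age, year) unname(total_per_year * share[as.character(age)])
}

#' Simulate a Lexis table (and death records) with known truth
#'
#' Generates deaths per (age, period) cell as independent Poisson counts
#' with mean `N * exp(age_log_rate + period_log_rr + cohort_log_rr)` where
#' `N` is the live-birth exposure of the cell and `cohort = period - age` —
#' exactly the data-generating process the APC model assumes. Optionally
#' emits the corresponding record-level death stream with covariate labels
#' assigned uniformly at random (or per supplied probabilities), for
#' exercising the tabulation and group-comparison machinery.
#'
#' @param truth a [true_effects()] object.
#' @param exposure exposure function `f(age, year)`, e.g.
#'   [exposure_uniform()] or [exposure_unimodal()].
#' @param age_range,period_range inclusive integer ranges.
#' @param seed integer seed; the simulation is fully deterministic given it.
#' @param records also generate the record-level death stream.
#' @param covariate_probs optional named list of probability vectors over
#'   the canonical covariate levels; default uniform.
#' @return list with `table` (a [lexis_table()]), `records` (data.frame or
#'   `NULL`), `truth`, `seed`.
#' @export
simulate_lexis <- function(truth = true_effects(),
                           exposure = exposure_uniform(),
                           age_range = c(10, 54),
                           period_range = c(2002, 2014),
                           seed,
                           records = FALSE,
                           covariate_probs = NULL) {
  stopifnot(inherits(truth, "true_effects"), !missing(seed))
  set.seed(as.integer(seed))
  ages <- seq.int(age_range[1], age_range[2])
  periods <- seq.int(period_range[1], period_range[2])
  grid <- expand.grid(age = ages, period = periods, KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$period, grid$age), ]
  grid$cohort <- grid$period - grid$age
  N <- exposure(grid$age, grid$period)
  stopifnot(all(is.finite(N)), all(N >= 0))
  log_lambda <- truth$age_log_rate(grid$age) +
    truth$period_log_rr(grid$period) +
    truth$cohort_log_rr(grid$cohort)
  mu <- N * exp(log_lambda)
  if (any(!is.finite(mu)) || any(mu > .Machine$integer.max))
    stop("expected deaths overflow; rescale the truth or exposure")
  grid$deaths <- stats::rpois(nrow(grid), mu)
  grid$exposure <- N
  keep <- grid$exposure > 0
  tab <- lexis_table(grid[keep, c("age", "period", "cohort",
                                  "deaths", "exposure")])
  attr(tab, "expected_deaths") <- mu[keep]

  recs <- NULL
  if (records) {
    idx <- rep.int(seq_len(nrow(tab)), tab$deaths)
    lv <- covariate_levels()
    draw <- function(var) {
      p <- covariate_probs[[var]]
      if (is.null(p)) p <- rep(1 / length(lv[[var]]), length(lv[[var]]))
      sample(lv[[var]], length(idx), replace = TRUE, prob = p)
    }
    recs <- data.frame(age = tab$age[idx], year = tab$period[idx],
                       schooling = draw("schooling"),
                       marginalization = draw("marginalization"),
                       medical_care = draw("medical_care"),
                       affiliation = draw("affiliation"),
                       stringsAsFactors = FALSE)
  }
  list(table = tab, records = recs, truth = truth, seed = as.integer(seed))
}

#' Simulate two groups of annual death counts
#'
#' Two independent Normal samples rounded to non-negative integers —
#' fixtures for the group-comparison t machinery.
#'
#' @param mu_a,mu_b group means.
#' @param sd common standard deviation (>= 0).
#' @param n observations per group (>= 2), e.g. 13 calendar years.
#' @param seed integer seed.
#' @return list with numeric vectors `a` and `b`.
#' @export
simulate_group_counts <- function(mu_a, mu_b, sd, n, seed) {
  stopifnot(sd >= 0, n >= 2)
  set.seed(as.integer(seed))
  list(a = pmax(0, round(stats::rnorm(n, mu_a, sd))),
       b = pmax(0, round(stats::rnorm(n, mu_b, sd))))
}

#' Parameter-recovery study for the APC model
#'
#' Simulates `n_replicates` Lexis tables from a known truth, fits the APC
#' model to each, and summarizes how well the generator's parameters are
#' recovered: bias and coverage of the drift estimate, log-scale errors of
#' the age-rate curve at probe ages, and the qualitative U-shape check
#' (higher estimated rates at the young/old probes than at the minimum).
#' Replicate `r` uses child seed `seed + r` (documented counter scheme), so
#' any replicate is reproducible in isolation. Fit failures are caught,
#' counted and reported — never silently dropped.
#'
#' @param n_replicates number of replicates, >= 10.
#' @param truth a [true_effects()] object.
#' @param spec an [apc_spec()].
#' @param seed integer root seed.
#' @param exposure exposure function (default uniform 100,000 births/cell).
#' @param age_range,period_range simulation ranges.
#' @param probe_ages ages at which the age curve is probed.
#' @return list of class `recovery_report`: per-replicate data.frame
#'   `replicates`, and summary fields `drift_truth`, `drift_mean`,
#'   `drift_bias`, `drift_rmse`, `drift_coverage` (count of replicates
#'   whose CI covers the truth), `age_rmse_log` (per probe age),
#'   `age_shape_count` (replicates with rate(13), rate(42) > rate(27)
#'   analogue at the outer/inner probes), `n_failed`, `n_ok`.
#' @export
recovery_report <- function(n_replicates, truth = true_effects(),
                            spec = apc_spec(), seed,
                            exposure = exposure_uniform(1e5),
                            age_range = c(10, 54),
                            period_range = c(2002, 2014),
                            probe_ages = c(13, 20, 27, 35, 42)) {
  stopifnot(n_replicates >= 10, !missing(seed))
  truth_age_log <- truth$age_log_rate(probe_ages)
  rows <- vector("list", n_replicates)
  n_failed <- 0L
  for (r in seq_len(n_replicates)) {
    sim <- simulate_lexis(truth, exposure, age_range, period_range,
                          seed = seed + r)
    fit <- tryCatch(apc_fit(sim$table, spec), error = function(e) e)
    if (inherits(fit, "error")) {
      n_failed <- n_failed + 1L
      rows[[r]] <- data.frame(replicate = r, ok = FALSE, drift_est = NA,
                              drift_se = NA, covered = NA,
                              shape_ok = NA,
                              t(stats::setNames(rep(NA_real_,
                                                    length(probe_ages)),
                                                paste0("age_", probe_ages))),
                              check.names = FALSE)
      next
    }
    d <- drift(fit)
    curve <- age_effect(fit, grid = probe_ages)
    est_log <- log(curve$estimate / spec$rate_scale)
    inner <- which.min(abs(probe_ages - truth$age_min_at))
    shape_ok <- all(curve$estimate[c(1, length(probe_ages))] >
                      curve$estimate[inner])
    rows[[r]] <- data.frame(replicate = r, ok = TRUE,
                            drift_est = d$estimate, drift_se = d$se,
                            covered = d$ci[1] <= truth$cohort_drift &&
                                      truth$cohort_drift <= d$ci[2],
                            shape_ok = shape_ok,
                            t(stats::setNames(est_log,
                                              paste0("age_", probe_ages))),
                            check.names = FALSE)
  }
  rep_df <- do.call(rbind, rows)
  ok <- rep_df$ok
  age_cols <- paste0("age_", probe_ages)
  age_err <- sweep(as.matrix(rep_df[ok, age_cols, drop = FALSE]), 2L,
                   truth_age_log, "-")
  structure(list(
    replicates = rep_df,
    drift_truth = truth$cohort_drift,
    drift_mean = mean(rep_df$drift_est[ok]),
    drift_bias = mean(rep_df$drift_est[ok]) - truth$cohort_drift,
    drift_rmse = sqrt(mean((rep_df$drift_est[ok] - truth$cohort_drift)^2)),
    drift_coverage = sum(rep_df$covered[ok]),
    age_rmse_log = sqrt(colMeans(age_err^2)),
    age_shape_count = sum(rep_df$shape_ok[ok]),
    probe_ages = probe_ages,
    n_ok = sum(ok), n_failed = n_failed, seed = seed
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%d failed)\n",
              x$n_ok + x$n_failed, x$n_failed))
  cat(sprintf("  drift: truth %.4f, mean estimate %.4f (bias %+.5f, rmse %.5f)\n",
              x$drift_truth, x$drift_mean, x$drift_bias, x$drift_rmse))
  cat(sprintf("  drift CI coverage: %d / %d\n", x$drift_coverage, x$n_ok))
  cat(sprintf("  age U-shape recovered in %d / %d replicates\n",
              x$age_shape_count, x$n_ok))
  cat("  age-curve RMSE (log scale) at probe ages:\n")
  print(round(x$age_rmse_log, 4))
  invisible(x)
}
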