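#' Age-period-cohort model specification
#'
#' Collects the configuration of the identifiable APC Poisson rate model:
#' knot counts per time dimension, the reference cohort at which the cohort
#' rate ratio is anchored to 1, the reporting scale for rates, and fitter
#' controls.
#'
#' The identification convention (the part of any APC analysis that is pure
#' convention and must be stated): the intercept and the age slope live in
#' the age block; the single secular log-linear trend (drift) is attributed
#' to cohort; the period block is detrended (orthogonal to level and trend,
#' so period effects are trend-free rate ratios averaging to 1); and the
#' cohort curvature block is detrended and anchored at the reference
#' cohort, so the cohort rate ratio is exactly 1 there.
#'
#' @param n_knots named integer vector with elements `age`, `period`,
#'   `cohort` (each >= 3). The defaults 6/6/6 yield a 15-column design:
#'   6 age columns (incl. the intercept), 4 detrended period columns, and
#'   1 drift + 4 curvature cohort columns.
#' @param reference_cohort birth year at which the cohort rate ratio is
#'   pinned to 1 (default 1980).
#' @param rate_scale multiplier for reported age-specific rates (default
#'   100,000: deaths per 100,000 live births).
#' @param ci_level pointwise confidence level for effect bands.
#' @param max_iter,tol IRLS controls: iteration cap and convergence
#'   tolerance on the relative deviance change / score norm.
#' @param weighted_detrend logical; project trends out with
#'   exposure-weighted inner products instead of ordinary ones.
#' @return a list with class `apc_spec`.
#' @export
apc_spec <- function(n_knots = c(age = 6L, period = 6L, cohort = 6L),
                     reference_cohort = 1980,
                     rate_scale = 1e5,
                     ci_level = 0.95,
                     max_iter = 100L,
                     tol = 1e-8,
                     weighted_detrend = FALSE) {
  stopifnot(all(c("age", "period", "cohort") %in% names(n_knots)),
            all(n_knots >= 3L),
            rate_scale > 0, tol > 0, max_iter >= 1L,
            ci_level > 0, ci_level < 1)
  structure(list(n_knots = n_knots, reference_cohort = reference_cohort,
                 rate_scale = rate_scale, ci_level = ci_level,
                 max_iter = as.integer(max_iter), tol = tol,
                 weighted_detrend = weighted_detrend),
            class = "apc_spec")
}

#' Assemble the identifiable APC design matrix
#'
#' Builds the design matrix and offset for the Poisson rate model
#' `log E(D) = log N + mu + f_age(a) + f_period(p) + f_cohort(c)` from a
#' Lexis table, using restricted cubic spline bases with knots placed at
#' exposure-weighted quantiles:
#'
#' * age block: intercept column + full spline basis of age (linear +
#'   curvature) — carries the overall level and the age slope;
#' * period block: spline curvature columns of period, detrended so the
#'   block is orthogonal to `{1, period}` — no level, no trend;
#' * cohort block: a drift column `cohort - reference` carrying the secular
#'   trend, + spline curvature columns of cohort, detrended and anchored to
#'   0 at the reference cohort.
#'
#' Degenerate dimensions collapse gracefully: with too few distinct values
#' the spline part of a block shrinks (down to nothing for a single-valued
#' dimension) with a warning.
#'
#' @param table a [lexis_table()].
#' @param spec an [apc_spec()].
#' @return list of class `apc_design`: `X` (design matrix), `offset`
#'   (log exposure), `blocks` (column indices per block), `bases` (the
#'   stored spline bases for re-evaluation on grids), `spec`, `table`.
#' @export
build_design <- function(table, spec = apc_spec()) {
  stopifnot(inherits(table, "lexis_table"), nrow(table) > 0,
            inherits(spec, "apc_spec"))
  w <- table$exposure
  dtw <- if (spec$weighted_detrend) w else NULL
  ref <- spec$reference_cohort
  if (ref < min(table$cohort) || ref > max(table$cohort))
    stop("reference cohort ", ref, " outside the data cohort span [",
         min(table$cohort), ", ", max(table$cohort), "]")

  shrink <- function(dim_name, x, wanted) {
    nd <- length(unique(x))
    if (nd >= wanted) return(as.integer(wanted))
    if (nd < 3L) {
      warning(dim_name, " has ", nd,
              " distinct value(s); spline block collapsed")
      return(0L)
    }
    warning(dim_name, " has only ", nd, " distinct values; using ", nd,
            " knots instead of ", wanted)
    as.integer(nd)
  }

  # -- age block: intercept + full spline (linear + curvature)
  ka <- shrink("age", table$age, spec$n_knots[["age"]])
  if (ka > 0L) {
    age_basis <- rcs_basis(table$age, place_knots(table$age, ka, w))
    A <- unclass_matrix(age_basis)
  } else {
    age_basis <- NULL
    A <- NULL
  }
  age_block <- cbind(`(Intercept)` = rep(1, nrow(table)), A)
  if (!is.null(A))
    colnames(age_block) <- c("(Intercept)", paste0("age_", colnames(A)))

  # -- period block: curvature columns only, detrended
  kp <- shrink("period", table$period, spec$n_knots[["period"]])
  if (kp >= 3L) {
    p_raw <- rcs_basis(table$period, place_knots(table$period, kp, w))
    p_curv <- basis_subset(p_raw, -1L)
    period_basis <- detrend(p_curv, weights = dtw)
    P <- unclass_matrix(period_basis)
    colnames(P) <- paste0("per_", colnames(P))
  } else {
    if (kp > 0L)
      warning("period spline needs >= 3 knots; period block collapsed")
    period_basis <- NULL
    P <- NULL
  }

  # -- cohort block: drift + detrended, reference-anchored curvature
  kc <- shrink("cohort", table$cohort, spec$n_knots[["cohort"]])
  drift_col <- matrix(table$cohort - ref, ncol = 1,
                      dimnames = list(NULL, "coh_drift"))
  if (kc >= 3L) {
    c_raw <- rcs_basis(table$cohort, place_knots(table$cohort, kc, w))
    c_curv <- basis_subset(c_raw, -1L)
    cohort_basis <- set_reference(detrend(c_curv, weights = dtw), ref)
    C <- unclass_matrix(cohort_basis)
    colnames(C) <- paste0("coh_", colnames(C))
  } else {
    if (kc > 0L)
      warning("cohort spline needs >= 3 knots; curvature block collapsed")
    cohort_basis <- NULL
    C <- NULL
  }
  cohort_block <- cbind(drift_col, C)

  # with a single age, cohort == period - const: the period and cohort
  # curvature blocks span the same functions, so keep only the cohort block
  if (length(unique(table$age)) == 1L && !is.null(P) && !is.null(C)) {
    warning("single-age table: period and cohort coincide; period block dropped")
    P <- NULL
    period_basis <- NULL
  }

  X <- cbind(age_block, P, cohort_block)
  blocks <- list(
    age = seq_len(ncol(age_block)),
    period = if (is.null(P)) integer(0)
             else ncol(age_block) + seq_len(ncol(P)),
    cohort = ncol(age_block) + NCOL2(P) + seq_len(ncol(cohort_block))
  )
  check_design_rank(X, blocks)

  structure(list(X = X, offset = log(table$exposure), blocks = blocks,
                 bases = list(age = age_basis, period = period_basis,
                              cohort = cohort_basis),
                 spec = spec, table = table),
            class = "apc_design")
}

NCOL2 <- function(m) if (is.null(m)) 0L else ncol(m)

# full-rank check with per-block attribution of any deficiency
check_design_rank <- function(X, blocks) {
  qx <- qr(X)
  if (qx$rank == ncol(X)) return(invisible(TRUE))
  held <- 0L
  for (b in names(blocks)) {
    idx <- seq_len(max(c(0L, blocks[[b]])))
    r <- qr(X[, idx, drop = FALSE])$rank
    if (r < length(idx) && r <= held + length(blocks[[b]]) - 1L)
      stop("design matrix is rank deficient: ", b,
           " block introduces a collinear direction (rank ", qx$rank,
           " < ", ncol(X), " columns)")
    held <- r
  }
  stop("design matrix is rank deficient (rank ", qx$rank, " < ",
       ncol(X), " columns)")
}

#' Fit a Poisson rate model by IRLS
#'
#' Maximizes the Poisson log-likelihood
#' `sum(D * (X b + offset) - exp(X b + offset) - log(D!))`
#' by iteratively reweighted least squares with a log link and fixed
#' offset. Convergence is declared when the relative deviance change or
#' the maximum absolute score falls below `tol`. The intercept (if the
#' design has a constant column) is initialized at `log(sum(D)/sum(N))`,
#' all other coefficients at zero.
#'
#' @param design an `apc_design` from [build_design()], or any list with
#'   elements `X`, `offset` (and optionally `spec`).
#' @param deaths non-negative counts aligned with the design rows; defaults
#'   to the Lexis table stored in the design.
#' @return list of class `apc_fit`: `beta`, `cov` (inverse observed Fisher
#'   information), `fitted` (expected counts), `loglik`, `deviance`, `aic`,
#'   `bic`, `n_obs`, `n_iter`, `converged`, `deviance_trace`, plus the
#'   design for effect extraction.
#' @export
fit_poisson <- function(design, deaths = design$table$deaths) {
  X <- design$X
  off <- design$offset
  y <- as.numeric(deaths)
  stopifnot(length(y) == nrow(X), all(y >= 0), all(is.finite(off)))
  spec <- design$spec
  tol <- if (is.null(spec)) 1e-8 else spec$tol
  max_iter <- if (is.null(spec)) 100L else spec$max_iter

  p <- ncol(X)
  beta <- numeric(p)
  const_col <- which(apply(X, 2L, function(col) all(col == col[1L]) &&
                                  col[1L] != 0))[1L]
  if (!is.na(const_col) && sum(y) > 0)
    beta[const_col] <- log(sum(y) / sum(exp(off))) / X[1L, const_col]

  dev_fun <- function(mu) {
    2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
  }
  eta <- drop(X %*% beta) + off
  mu <- exp(eta)
  dev <- dev_fun(mu)
  trace <- dev
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    w <- mu
    z <- (eta - off) + (y - mu) / mu
    fit <- stats::lm.wfit(X, z, w = w)
    if (any(is.na(fit$coefficients)))
      stop("IRLS: design became numerically singular at iteration ", it)
    beta_new <- fit$coefficients
    if (sqrt(sum(beta_new^2)) > 1e4)
      stop("IRLS: diverging coefficients (possible separation or ",
           "degenerate exposure); |beta| = ", signif(sqrt(sum(beta_new^2))))
    # step-halving keeps the deviance non-increasing
    step <- beta_new - beta
    h <- 1
    repeat {
      cand <- beta + h * step
      eta_c <- drop(X %*% cand) + off
      mu_c <- exp(eta_c)
      dev_c <- dev_fun(mu_c)
      if (is.finite(dev_c) && dev_c <= dev * (1 + 1e-12) || h < 1e-8) break
      h <- h / 2
    }
    beta <- cand; eta <- eta_c; mu <- mu_c
    dev_old <- dev; dev <- dev_c
    trace <- c(trace, dev)
    score <- drop(crossprod(X, y - mu))
    if (abs(dev_old - dev) / (abs(dev_old) + 0.1) < tol ||
        max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    err <- simpleError(paste0("IRLS did not converge in ", max_iter,
                              " iterations"))
    err$last_beta <- beta
    stop(err)
  }

  info <- crossprod(X * sqrt(mu))
  cov <- chol2inv(chol(info))
  dimnames(cov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  ll <- sum(stats::dpois(y, mu, log = TRUE))
  n <- length(y)
  structure(list(beta = beta, cov = cov, fitted = mu,
                 loglik = ll, deviance = dev,
                 aic = -2 * ll + 2 * p, bic = -2 * ll + p * log(n),
                 n_obs = n, n_iter = it, converged = converged,
                 deviance_trace = trace, design = design),
            class = "apc_fit")
}

#' Fit the APC model to a Lexis table
#'
#' Convenience wrapper: [build_design()] then [fit_poisson()].
#'
#' @inheritParams build_design
#' @return an `apc_fit`.
#' @export
apc_fit <- function(table, spec = apc_spec()) {
  fit_poisson(build_design(table, spec))
}

#' @export
print.apc_fit <- function(x, ...) {
  cat("Age-period-cohort Poisson rate model\n")
  cat(sprintf("  %d cells, %d parameters, %d IRLS iterations\n",
              x$n_obs, length(x$beta), x$n_iter))
  cat(sprintf("  log-likelihood %.4f, deviance %.4f, AIC %.2f, BIC %.2f\n",
              x$loglik, x$deviance, x$aic, x$bic))
  d <- drift(x)
  cat(sprintf("  cohort drift %.4f per year (se %.4f, z %.2f)\n",
              d$estimate, d$se, d$z))
  invisible(x)
}

effect_curve_df <- function(x, eta, var_eta, level, scale_name, mult = 1) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  se <- sqrt(pmax(var_eta, 0))
  out <- data.frame(x = x,
                    estimate = mult * exp(eta),
                    lower = mult * exp(eta - z * se),
                    upper = mult * exp(eta + z * se))
  attr(out, "scale") <- scale_name
  attr(out, "ci_level") <- level
  class(out) <- c("effect_curve", "data.frame")
  out
}

block_curve <- function(fit, rows_fun, block, grid, scale_name, mult = 1) {
  stopifnot(inherits(fit, "apc_fit"))
  if (!fit$converged) stop("fit did not converge")
  idx <- fit$design$blocks[[block]]
  R <- rows_fun(grid)
  eta <- drop(R %*% fit$beta[idx])
  V <- fit$cov[idx, idx, drop = FALSE]
  var_eta <- rowSums((R %*% V) * R)
  effect_curve_df(grid, eta, var_eta, fit$design$spec$ci_level,
                  scale_name, mult)
}

check_grid <- function(grid, lo, hi, what, extrapolate) {
  if (!extrapolate && (min(grid) < lo || max(grid) > hi))
    stop(what, " grid extends outside the data range [", lo, ", ", hi,
         "]; set extrapolate = TRUE to evaluate the linear tails anyway")
}

#' Age effect: fitted age-specific mortality rate
#'
#' Evaluates the fitted age-specific rate (per `rate_scale` live births) at
#' the reference cohort and trend-free average period, with pointwise
#' delta-method confidence bands on the log scale.
#'
#' @param fit an `apc_fit`.
#' @param grid ages to evaluate at; defaults to a 0.25-year grid over the
#'   observed age range.
#' @param extrapolate allow evaluation outside the observed range (the
#'   spline is linear beyond the boundary knots).
#' @return data.frame of class `effect_curve` with columns `x`, `estimate`,
#'   `lower`, `upper`; attribute `scale = "rate_per_100k"` style label.
#' @export
age_effect <- function(fit, grid = NULL, extrapolate = FALSE) {
  tab <- fit$design$table
  if (is.null(grid))
    grid <- seq(min(tab$age), max(tab$age), by = 0.25)
  check_grid(grid, min(tab$age), max(tab$age), "age", extrapolate)
  b <- fit$design$bases$age
  rows_fun <- function(g) {
    if (is.null(b)) matrix(1, length(g), 1) else cbind(1, eval_basis(b, g))
  }
  block_curve(fit, rows_fun, "age", grid,
              scale_name = "rate_per_100k",
              mult = fit$design$spec$rate_scale)
}

#' Period effect: trend-free rate ratio by calendar year
#'
#' Evaluates the fitted period rate ratio (relative to the period average;
#' the detrended block carries no level or trend by construction).
#'
#' @inheritParams age_effect
#' @return an `effect_curve` with `scale = "rate_ratio"`.
#' @export
period_effect <- function(fit, grid = NULL, extrapolate = FALSE) {
  tab <- fit$design$table
  if (is.null(grid))
    grid <- seq(min(tab$period), max(tab$period), by = 0.25)
  check_grid(grid, min(tab$period), max(tab$period), "period", extrapolate)
  b <- fit$design$bases$period
  rows_fun <- function(g) {
    if (is.null(b)) matrix(0, length(g), 0) else eval_basis(b, g)
  }
  if (is.null(b))
    return(effect_curve_df(grid, rep(0, length(grid)), rep(0, length(grid)),
                           fit$design$spec$ci_level, "rate_ratio"))
  block_curve(fit, rows_fun, "period", grid, scale_name = "rate_ratio")
}

#' Cohort effect: rate ratio relative to the reference cohort
#'
#' Evaluates the fitted cohort rate ratio
#' `exp(drift * (cohort - reference) + curvature(cohort))`, which equals
#' exactly 1 at the reference cohort (the curvature basis is anchored
#' there and the drift term vanishes).
#'
#' @inheritParams age_effect
#' @return an `effect_curve` with `scale = "rate_ratio"`.
#' @export
cohort_effect <- function(fit, grid = NULL, extrapolate = FALSE) {
  tab <- fit$design$table
  if (is.null(grid))
    grid <- seq(min(tab$cohort), max(tab$cohort), by = 0.25)
  check_grid(grid, min(tab$cohort), max(tab$cohort), "cohort", extrapolate)
  ref <- fit$design$spec$reference_cohort
  b <- fit$design$bases$cohort
  rows_fun <- function(g) {
    dr <- matrix(g - ref, ncol = 1)
    if (is.null(b)) dr else cbind(dr, eval_basis(b, g))
  }
  block_curve(fit, rows_fun, "cohort", grid, scale_name = "rate_ratio")
}

#' Secular drift of the cohort effect
#'
#' Returns the drift coefficient — the identifiable secular log-linear
#' trend of mortality per cohort year, allocated to the cohort block — with
#' its standard error, Wald z and confidence interval.
#'
#' @param fit an `apc_fit`.
#' @param level confidence level; defaults to the spec's `ci_level`.
#' @return list with `estimate`, `se`, `z`, `ci` (length-2), `level`.
#' @export
drift <- function(fit, level = fit$design$spec$ci_level) {
  stopifnot(inherits(fit, "apc_fit"))
  if (!fit$converged) stop("fit did not converge")
  i <- which(names(fit$beta) == "coh_drift")
  est <- unname(fit$beta[i])
  se <- sqrt(fit$cov[i, i])
  zq <- stats::qnorm(1 - (1 - level) / 2)
  list(estimate = est, se = se,
       z = if (se > 0) est / se else NaN,
       ci = c(est - zq * se, est + zq * se),
       level = level)
}

#' @export
print.effect_curve <- function(x, ...) {
  cat(sprintf("Effect curve (%s), %d points, %.0f%% bands\n",
              attr(x, "scale"), nrow(x), 100 * attr(x, "ci_level")))
  NextMethod()
}
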