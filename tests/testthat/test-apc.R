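# independent brute-force maximizer of the same Poisson likelihood
oracle_mle <- function(X, off, y, start = NULL) {
  nll <- function(b) {
    eta <- drop(X %*% b) + off
    -sum(y * eta - exp(eta))
  }
  gr <- function(b) -drop(crossprod(X, y - exp(drop(X %*% b) + off)))
  if (is.null(start)) start <- numeric(ncol(X))
  opt <- optim(start, nll, gr, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  opt$par
}

small_design <- function(X, off) {
  list(X = X, offset = off, spec = apc_spec())
}

test_that("design matrix has the 15-column block layout and is identified", {
  sim <- fixture_sim(seed = 2)
  des <- build_design(sim$table, apc_spec())
  expect_equal(ncol(des$X), 15L)
  expect_length(des$blocks$age, 6L)      # intercept + 5 spline columns
  expect_length(des$blocks$period, 4L)   # detrended curvature
  expect_length(des$blocks$cohort, 5L)   # drift + 4 anchored curvature
  expect_equal(qr(des$X)$rank, 15L)
  # period block orthogonal to {1, period}
  P <- des$X[, des$blocks$period]
  expect_lt(max(abs(crossprod(cbind(1, sim$table$period), P))), 1e-8)
  # cohort curvature zero at the reference cohort
  curv <- des$bases$cohort
  expect_lt(max(abs(eval_basis(curv, 1980))), 1e-10)
  expect_equal(des$offset, log(sim$table$exposure))
})

test_that("degenerate single-age table collapses the age block", {
  df <- data.frame(age = 20, period = 2002:2014, cohort = 1982:1994,
                   deaths = rpois(13, 5), exposure = 1e4)
  tab <- lexis_table(df)
  expect_warning(
    des <- build_design(tab, apc_spec(reference_cohort = 1988)), "age")
  expect_equal(colnames(des$X)[des$blocks$age], "(Intercept)")
})

test_that("constant-only fit recovers the pooled-rate MLE in closed form", {
  des <- small_design(matrix(1, 2, 1, dimnames = list(NULL, "(Intercept)")),
                      off = log(c(10000, 10000)))
  fit <- fit_poisson(des, deaths = c(2, 3))
  expect_equal(unname(fit$beta), log(2.5e-4), tolerance = 1e-10)
  expect_equal(sum(fit$fitted), 5, tolerance = 1e-8)
})

test_that("IRLS matches a brute-force likelihood maximizer", {
  set.seed(33)
  for (p in c(2, 3, 5)) {
    n <- 50
    X <- cbind(1, matrix(rnorm(n * (p - 1), sd = 0.5), n))
    colnames(X) <- c("(Intercept)", paste0("x", seq_len(p - 1)))
    off <- log(runif(n, 500, 5000))
    beta_true <- c(-6, rnorm(p - 1, sd = 0.3))
    y <- rpois(n, exp(drop(X %*% beta_true) + off))
    fit <- fit_poisson(small_design(X, off), deaths = y)
    expect_lt(max(abs(unname(fit$beta) - oracle_mle(X, off, y, fit$beta * 0))),
              1e-6)
    # intercept score equation: fitted total equals observed total
    expect_equal(sum(fit$fitted), sum(y), tolerance = 1e-6 * sum(y))
  }
})

test_that("IRLS deviance is non-increasing and fit statistics are coherent", {
  sim <- fixture_sim(seed = 8)
  fit <- apc_fit(sim$table)
  expect_true(fit$converged)
  expect_true(all(diff(fit$deviance_trace) <= 1e-8))
  p <- length(fit$beta)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * p)
  expect_equal(fit$bic, -2 * fit$loglik + p * log(fit$n_obs))
  # covariance symmetric positive definite
  expect_equal(fit$cov, t(fit$cov), tolerance = 1e-10)
  expect_true(all(eigen(fit$cov, symmetric = TRUE,
                        only.values = TRUE)$values > 0))
  # glm cross-check on the same design
  glmfit <- glm(sim$table$deaths ~ fit$design$X - 1 +
                  offset(log(sim$table$exposure)), family = poisson())
  expect_equal(unname(fit$beta), unname(coef(glmfit)), tolerance = 1e-6)
})

test_that("fitted cell rates are invariant to trend re-allocation", {
  # the APC non-identifiability acts on the decomposition, never the fit:
  # un-detrending the period block changes the blocks' meaning but spans
  # the same column space (period trend = age trend + cohort trend), so
  # the fitted rates must not move.
  sim <- fixture_sim(seed = 13)
  des <- build_design(sim$table, apc_spec())
  fit <- fit_poisson(des)

  des2 <- des
  p_raw <- rcs_basis(sim$table$period,
                     place_knots(sim$table$period, 6, sim$table$exposure))
  des2$X[, des2$blocks$period] <- apcmort:::unclass_matrix(p_raw)[, -1]
  expect_equal(qr(des2$X)$rank, ncol(des2$X))
  fit2 <- fit_poisson(des2)
  expect_lt(max(abs(fit2$fitted - fit$fitted) / fit$fitted), 1e-8)
})

test_that("effect curves carry the stated scales, anchors and CIs", {
  sim <- fixture_sim(seed = 4)
  fit <- apc_fit(sim$table)

  # cohort RR is exactly 1 at the 1980 reference with zero-width CI
  ce <- cohort_effect(fit, grid = c(1960, 1980, 2000))
  expect_equal(ce$estimate[ce$x == 1980], 1)
  expect_equal(ce$lower[ce$x == 1980], 1)
  expect_equal(ce$upper[ce$x == 1980], 1)
  expect_true(all(ce$lower <= ce$estimate & ce$estimate <= ce$upper))

  # declining cohort truth: pre-1980 cohorts carry RR > 1
  expect_gt(ce$estimate[ce$x == 1960], 1)
  expect_lt(ce$estimate[ce$x == 2000], 1)

  # period log-RR averages to zero over the observed periods
  pe <- period_effect(fit, grid = 2002:2014)
  expect_lt(abs(mean(log(pe$estimate))), 1e-8)

  # U-shaped age truth: rates at 13 and 42 above the minimum at 27
  ae <- age_effect(fit, grid = c(13, 27, 42))
  expect_gt(ae$estimate[1], ae$estimate[2])
  expect_gt(ae$estimate[3], ae$estimate[2])

  # delta-method CI at one grid point recomputed by hand
  idx <- fit$design$blocks$age
  row <- cbind(1, eval_basis(fit$design$bases$age, 42))
  eta <- drop(row %*% fit$beta[idx])
  se <- sqrt(drop(row %*% fit$cov[idx, idx] %*% t(row)))
  z <- qnorm(0.975)
  expect_equal(ae$estimate[3], 1e5 * exp(eta), tolerance = 1e-10)
  expect_equal(ae$lower[3], 1e5 * exp(eta - z * se), tolerance = 1e-10)
  expect_equal(ae$upper[3], 1e5 * exp(eta + z * se), tolerance = 1e-10)

  # degenerate covariance: bands collapse onto the estimate
  fit0 <- fit
  fit0$cov[] <- 0
  ae0 <- age_effect(fit0, grid = c(13, 27, 42))
  expect_equal(ae0$lower, ae0$estimate)
  expect_equal(ae0$upper, ae0$estimate)

  # no silent extrapolation
  expect_error(age_effect(fit, grid = c(5, 30)), "extrapolate")
  expect_silent(age_effect(fit, grid = c(5, 30), extrapolate = TRUE))
})

test_that("drift reports the Table-style summary quantities", {
  sim <- fixture_sim(seed = 21)
  fit <- apc_fit(sim$table)
  d <- drift(fit)
  expect_equal(d$z, d$estimate / d$se)
  expect_equal(d$ci, d$estimate + c(-1, 1) * qnorm(0.975) * d$se)
  # cross-check the Wald interval against a profile-likelihood interval
  des <- fit$design
  i <- which(colnames(des$X) == "coh_drift")
  prof_dev <- function(val) {
    Xr <- des$X[, -i, drop = FALSE]
    offr <- des$offset + des$X[, i] * val
    f <- fit_poisson(list(X = Xr, offset = offr, spec = des$spec),
                     deaths = sim$table$deaths)
    -2 * f$loglik
  }
  target <- -2 * fit$loglik + qchisq(0.95, 1)
  lo <- uniroot(function(v) prof_dev(v) - target,
                c(d$ci[1] - 5 * d$se, d$estimate))$root
  hi <- uniroot(function(v) prof_dev(v) - target,
                c(d$estimate, d$ci[2] + 5 * d$se))$root
  expect_lt(max(abs(d$ci - c(lo, hi))), 0.01)
})
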