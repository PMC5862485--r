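#' Summary of annual death counts for one group
#'
#' Mean and standard error of the mean of a group's annual observations
#' (sample standard deviation, n - 1 denominator).
#'
#' @param x numeric vector of annual death counts, length >= 2.
#' @param label optional group label.
#' @return list with `n`, `mean`, `sd`, `se`, `label`.
#' @examples
#' group_summary(c(1, 2, 3))  # mean 2, se 1/sqrt(3)
#' @export
group_summary <- function(x, label = deparse(substitute(x))) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 observations")
  if (anyNA(x)) stop("missing values in x")
  s <- stats::sd(x)
  list(n = length(x), mean = mean(x), sd = s, se = s / sqrt(length(x)),
       label = label)
}

#' Equal-variance two-sample t test on mean annual deaths
#'
#' Unpaired two-sample t test assuming equal variances: the pooled variance
#' is `((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a + n_b - 2)`, the degrees of
#' freedom `n_a + n_b - 2`. Reports the two-sided p-value together with
#' both one-sided p-values (`Pr(T > t)` and `Pr(T < t)`), and the
#' confidence interval for the mean difference.
#'
#' Setting `welch = TRUE` switches to the unequal-variance (Welch) test
#' with Satterthwaite degrees of freedom.
#'
#' @param a,b numeric samples (e.g. the 13 annual death counts 2002-2014
#'   for two categories), each of length >= 2.
#' @param ci_level confidence level for the difference interval.
#' @param welch use the Welch test instead of the pooled test.
#' @return list of class `mean_diff_test` with `difference`, `se_diff`,
#'   `df`, `t`, `p_two`, `p_upper`, `p_lower`, `ci`, `ci_level`,
#'   `mean_a`, `mean_b`, `n_a`, `n_b`.
#' @export
pooled_t_test <- function(a, b, ci_level = 0.95, welch = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  na <- length(a); nb <- length(b)
  va <- stats::var(a); vb <- stats::var(b)
  diff <- mean(a) - mean(b)
  if (welch) {
    se2 <- va / na + vb / nb
    se_diff <- sqrt(se2)
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se_diff <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- na + nb - 2
  }
  if (se_diff == 0) {
    if (diff != 0)
      stop("degenerate: zero pooled variance with unequal means")
    tstat <- 0
  } else {
    tstat <- diff / se_diff
  }
  p_lower <- stats::pt(tstat, df)       # Pr(T < t)
  p_upper <- 1 - p_lower                # Pr(T > t)
  tq <- stats::qt(1 - (1 - ci_level) / 2, df)
  structure(list(difference = diff, se_diff = se_diff, df = df, t = tstat,
                 p_two = 2 * min(p_upper, p_lower),
                 p_upper = p_upper, p_lower = p_lower,
                 ci = c(diff - tq * se_diff, diff + tq * se_diff),
                 ci_level = ci_level,
                 mean_a = mean(a), mean_b = mean(b), n_a = na, n_b = nb,
                 method = if (welch) "welch" else "pooled"),
            class = "mean_diff_test")
}

#' t statistic and p-values from a printed difference and standard error
#'
#' Entry point for working from published summary rows (a mean difference
#' and its standard error): `t = difference / se`. P-values use a
#' t reference distribution with `df` degrees of freedom; the default
#' `df = Inf` is the large-sample Normal reference.
#'
#' @param difference mean difference between the two groups.
#' @param se_diff standard error of the difference, strictly positive.
#' @param df degrees of freedom of the reference distribution.
#' @return list with `t`, `p_two`, `p_upper`, `p_lower`, `df`.
#' @examples
#' t_from_difference(2.008, 0.497)   # t = 4.040
#' @export
t_from_difference <- function(difference, se_diff, df = Inf) {
  if (!is.finite(se_diff) || se_diff <= 0)
    stop("se_diff must be strictly positive")
  tstat <- difference / se_diff
  p_lower <- stats::pt(tstat, df)
  list(t = tstat, p_two = 2 * min(p_lower, 1 - p_lower),
       p_upper = 1 - p_lower, p_lower = p_lower, df = df)
}

#' @export
print.mean_diff_test <- function(x, ...) {
  cat(sprintf("Two-sample %s-variance t test\n",
              if (x$method == "welch") "unequal" else "equal"))
  cat(sprintf("  means %.4f vs %.4f (n = %d, %d)\n",
              x$mean_a, x$mean_b, x$n_a, x$n_b))
  cat(sprintf("  difference %.4f (se %.4f), t = %.4f, df = %.4g\n",
              x$difference, x$se_diff, x$t, x$df))
  cat(sprintf("  Pr(|T|>|t|) = %.4g  Pr(T>t) = %.4g  Pr(T<t) = %.4g\n",
              x$p_two, x$p_upper, x$p_lower))
  cat(sprintf("  %.0f%% CI for difference: (%.4f, %.4f)\n",
              100 * x$ci_level, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Compare mean annual deaths between two categories of a covariate
#'
#' Convenience wrapper for record-level data: counts deaths per calendar
#' year within each of two covariate levels (levels absent in a year count
#' as 0) and runs [pooled_t_test()] on the two annual series.
#'
#' @param deaths data.frame of death records (columns `year` and the
#'   covariate named in `by`).
#' @param by covariate column name, e.g. `"schooling"`.
#' @param levels character vector of length 2: the two category levels (or
#'   level groups, given as list of character vectors) to compare.
#' @param years integer vector of calendar years defining the annual
#'   observations.
#' @param ci_level confidence level.
#' @return a `mean_diff_test` (see [pooled_t_test()]).
#' @export
compare_groups <- function(deaths, by, levels, years, ci_level = 0.95) {
  stopifnot(by %in% names(deaths), length(levels) == 2L)
  annual <- function(lv) {
    sel <- deaths[deaths[[by]] %in% lv & deaths$year %in% years, ]
    counts <- table(factor(sel$year, levels = years))
    as.numeric(counts)
  }
  a <- annual(levels[[1]])
  b <- annual(levels[[2]])
  pooled_t_test(a, b, ci_level = ci_level)
}
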