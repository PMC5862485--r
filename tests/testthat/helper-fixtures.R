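# Small in-code fixtures shared across test files.

# write a deaths CSV and return its path
write_deaths_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# a fully populated synthetic Lexis world (flat truth unless overridden)
fixture_sim <- function(seed = 42, ...) {
  simulate_lexis(truth = true_effects(...), exposure = exposure_uniform(1e5),
                 age_range = c(10, 54), period_range = c(2002, 2014),
                 seed = seed, records = TRUE)
}

# births data.frame covering a full grid with constant exposure
births_grid <- function(ages, years, births = 1e4) {
  g <- expand.grid(mother_age = ages, year = years, KEEP.OUT.ATTRS = FALSE)
  g$births <- births
  g
}

# independent truncated-power restricted-cubic oracle: for each interior
# knot t_m solve the 2x2 tail-restriction system for the coefficients of
# (x - t_{k-1})+^3 and (x - t_k)+^3 that cancel the cubic and quadratic
# terms beyond the last knot, then assemble numerically.
rcs_oracle <- function(x, knots) {
  k <- length(knots)
  pp <- function(u) pmax(u, 0)^3
  scl <- (knots[k] - knots[1])^2
  cols <- lapply(seq_len(k - 2), function(m) {
    # beyond t_k: (x-t)^3 = x^3 - 3 t x^2 + ...; require the x^3 and x^2
    # coefficients of 1*(x-t_m)^3 + a*(x-t_{k-1})^3 + b*(x-t_k)^3 to vanish
    A <- rbind(c(1, 1), -3 * c(knots[k - 1], knots[k]))
    rhs <- c(-1, 3 * knots[m])
    ab <- solve(A, rhs)
    (pp(x - knots[m]) + ab[1] * pp(x - knots[k - 1]) +
        ab[2] * pp(x - knots[k])) / scl
  })
  cbind(x, do.call(cbind, cols))
}
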