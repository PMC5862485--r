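test_that("knot placement hits quantiles of the weighted distribution", {
  expect_equal(place_knots(0:100, 3), c(0, 50, 100))
  expect_equal(place_knots(2002:2014, 5), c(2002, 2005, 2008, 2011, 2014))

  # exposure-weighted: all weight at or below 30 pulls interior knots <= 30
  x <- 0:100
  w <- ifelse(x <= 30, 1, 0)
  k <- place_knots(x, 5, weights = w)
  expect_equal(k[1], 0)
  expect_equal(k[5], 100)
  expect_true(all(k[2:4] <= 30))

  # brute-force weighted-quantile oracle: repeat each x by its (integer)
  # weight and take unweighted type-7 quantiles of the expansion
  set.seed(1)
  x2 <- sort(sample(0:50, 30))
  w2 <- sample(1:5, 30, replace = TRUE)
  k2 <- place_knots(x2, 4, weights = w2)
  expanded <- rep(x2, w2)
  oracle <- unname(quantile(expanded, c(0, 1/3, 2/3, 1), type = 7))
  expect_equal(k2[c(1, 4)], oracle[c(1, 4)])
  expect_equal(k2[2:3], oracle[2:3], tolerance = 2 / length(expanded) * diff(range(x2)))

  expect_error(place_knots(c(1, 1, 1, 2), 3), "distinct")
})

test_that("restricted cubic basis matches the truncated-power oracle", {
  set.seed(20)
  for (rep in 1:20) {
    x <- sort(runif(60, 0, 100))
    knots <- sort(sample(seq(5, 95, by = 5), 5))
    b <- rcs_basis(x, knots)
    expect_lt(max(abs(unclass(b) - rcs_oracle(x, knots))), 1e-8)
  }
})

test_that("basis is inactive below the first knot and linear beyond both", {
  knots <- c(10, 20, 30, 40, 50)
  x <- seq(0, 10, by = 0.5)           # entirely at/below the first knot
  b <- rcs_basis(x, knots)
  expect_true(all(unclass(b)[, -1] == 0))

  # second differences vanish on fine grids beyond either boundary knot
  for (grid in list(seq(50, 70, by = 1e-2), seq(-10, 10, by = 1e-2))) {
    bb <- unclass(rcs_basis(grid, knots))
    d2 <- diff(bb, differences = 2)
    expect_lt(max(abs(d2)), 1e-6)
  }
})

test_that("value, first and second derivatives are continuous at knots", {
  knots <- c(0, 13, 31, 55, 80, 100)
  h <- 1e-4
  for (t in knots) {
    g <- t + h * c(-2, -1, 0, 1, 2)
    bb <- unclass(rcs_basis(g, knots))
    for (j in seq_len(ncol(bb))) {
      v <- bb[, j]
      left_d <- (v[3] - v[1]) / (2 * h); right_d <- (v[5] - v[3]) / (2 * h)
      expect_lt(abs(left_d - right_d) * h, 1e-6)      # 1st derivative jump
      left_2 <- (v[1] - 2 * v[2] + v[3]) / h^2
      right_2 <- (v[3] - 2 * v[4] + v[5]) / h^2
      expect_lt(abs(left_2 - right_2) * h^2, 1e-6)    # 2nd derivative jump
    }
  }
})

test_that("detrend removes level and slope, verified against lm residuals", {
  set.seed(5)
  x <- sort(runif(50, 0, 10))
  b <- basis_subset(rcs_basis(x, c(0, 2.5, 5, 7.5, 10)), -1)
  db <- detrend(b)
  # Gram products with [1, x] vanish
  expect_lt(max(abs(crossprod(cbind(1, x), unclass(db)))), 1e-10)
  # explicit least-squares residual oracle
  for (j in seq_len(ncol(b))) {
    res <- residuals(lm(unclass(b)[, j] ~ x))
    expect_equal(unname(unclass(db)[, j]), unname(res), tolerance = 1e-10)
  }
  # idempotence: an already-detrended basis is returned unchanged
  db2 <- detrend(db)
  expect_equal(apcmort:::unclass_matrix(db2), apcmort:::unclass_matrix(db),
               tolerance = 1e-12)
  # a column that is exactly a + b x collapses -> error naming it
  fake <- rcs_basis(x, c(0, 2.5, 5, 7.5, 10))
  v <- apcmort:::unclass_matrix(fake)
  v[, "cub1"] <- 3 + 2 * x
  fake2 <- apcmort:::rebuild_basis(v, fake, meta = "raw")
  expect_error(detrend(fake2), "cub1")
})

test_that("reference anchoring zeroes the basis at x_ref and is idempotent", {
  x <- seq(1948, 2004)
  b <- detrend(basis_subset(rcs_basis(x, place_knots(x, 6)), -1))
  rb <- set_reference(b, 1980)
  # 1980 is an evaluation point: its row becomes all zeros
  expect_true(all(abs(unclass(rb)[x == 1980, ]) < 1e-12))
  # idempotence
  rb2 <- set_reference(rb, 1980)
  expect_equal(apcmort:::unclass_matrix(rb2), apcmort:::unclass_matrix(rb),
               tolerance = 1e-12)
  # any linear combination evaluates to 0 at x_ref (100 random coefficient sets)
  set.seed(9)
  row_ref <- eval_basis(rb, 1980)
  for (i in 1:100) {
    cc <- rnorm(ncol(rb))
    expect_lt(abs(drop(row_ref %*% cc)), 1e-10)
  }
  expect_error(set_reference(b, 1900), "outside")
})

test_that("eval_basis reproduces the stored matrix on the original grid", {
  x <- seq(10, 54)
  b <- set_reference(detrend(basis_subset(rcs_basis(x, place_knots(x, 6)), -1)), 30)
  expect_equal(unname(eval_basis(b, x)), unname(apcmort:::unclass_matrix(b)),
               tolerance = 1e-10)
})
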