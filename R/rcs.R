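#' Place spline knots at exposure-weighted quantiles
#'
#' Chooses `n_knots` knot positions for a restricted cubic spline: the
#' boundary knots sit at `min(x)` and `max(x)`, interior knots at equally
#' spaced quantiles of the (optionally exposure-weighted) distribution of
#' `x`. Under uniform weights the positions reproduce R's type-7 sample
#' quantiles, so a uniform grid gets equally spaced knots.
#'
#' @param x numeric values the spline will be evaluated on (e.g. ages).
#' @param n_knots integer number of knots, at least 3.
#' @param weights optional non-negative weights (e.g. live-birth exposure);
#'   `NULL` means uniform.
#' @return strictly increasing numeric vector of length `n_knots`.
#' @examples
#' place_knots(0:100, 3)           # 0, 50, 100
#' place_knots(2002:2014, 5)       # 2002, 2005, 2008, 2011, 2014
#' @export
place_knots <- function(x, n_knots, weights = NULL) {
  stopifnot(is.numeric(x), length(x) > 0L, all(is.finite(x)))
  n_knots <- as.integer(n_knots)
  if (n_knots < 3L) stop("n_knots must be at least 3")
  ux <- sort(unique(x))
  if (length(ux) < n_knots)
    stop("x has only ", length(ux), " distinct values; need at least ",
         n_knots, " to place knots")
  if (is.null(weights)) {
    k <- unname(stats::quantile(x, probs = seq(0, 1, length.out = n_knots),
                                type = 7, names = FALSE))
  } else {
    stopifnot(length(weights) == length(x), all(weights >= 0),
              sum(weights) > 0)
    k <- weighted_quantile(x, weights, seq(0, 1, length.out = n_knots))
  }
  k[1L] <- min(x)
  k[n_knots] <- max(x)
  # resolve ties by nudging duplicated knots onto unused data values
  if (any(diff(k) <= 0)) {
    out <- k[1L]
    for (i in 2L:n_knots) {
      ki <- k[i]
      if (ki <= out[i - 1L]) {
        cand <- ux[ux > out[i - 1L]]
        # keep room for the remaining knots (last must stay max(x))
        cand <- cand[seq_len(max(0L, length(cand) - (n_knots - i)))]
        if (length(cand) == 0L)
          stop("cannot resolve tied knots: too few distinct values of x")
        ki <- cand[1L]
      }
      out <- c(out, ki)
    }
    k <- out
    k[n_knots] <- max(x)
    if (any(diff(k) <= 0))
      stop("cannot resolve tied knots: too few distinct values of x")
  }
  k
}

# Linear-interpolation quantiles of the weighted empirical CDF, using
# type-7-style plotting positions F_i = (cumw_i - w_i) / (totw - w_n) so
# that uniform weights reduce exactly to stats::quantile(type = 7).
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w)
  denom <- cw[length(cw)] - w[length(w)]
  if (denom <= 0) return(rep(x[1L], length(probs)))
  Fi <- (cw - w) / denom
  Fi <- pmin(Fi, 1)
  vapply(probs, function(p) {
    i <- which(Fi >= p)[1L]
    if (is.na(i)) return(x[length(x)])
    if (i == 1L || Fi[i] == p) return(x[i])
    f0 <- Fi[i - 1L]; f1 <- Fi[i]
    if (f1 == f0) return(x[i - 1L])
    x[i - 1L] + (p - f0) / (f1 - f0) * (x[i] - x[i - 1L])
  }, numeric(1))
}

#' Restricted cubic spline basis
#'
#' Builds the restricted (natural) cubic spline basis on `x` for a given
#' knot vector: piecewise cubic, continuous through the second derivative
#' at every knot, and constrained to be linear beyond the boundary knots.
#' With `k` knots the basis has `k - 1` columns: the linear term `x` itself
#' followed by `k - 2` restricted truncated-power terms, each scaled by
#' `1 / (t_k - t_1)^2` so all columns live on comparable scales. The
#' constant is deliberately excluded (models supply their own intercept).
#'
#' The returned object remembers its knots and any subsequent detrending or
#' referencing transformation, so the same basis *functions* can be
#' re-evaluated on a new grid with [eval_basis()].
#'
#' @param x numeric evaluation points (all finite).
#' @param knots strictly increasing knot vector of length >= 3, e.g. from
#'   [place_knots()].
#' @return an object of class `rcs_basis`: the `n x (k-1)` basis matrix
#'   with attributes `x`, `knots`, `meta` (`"raw"`, `"detrended"` or
#'   `"referenced"`) and the stored transformation parameters.
#' @seealso [detrend()], [set_reference()], [eval_basis()]
#' @export
rcs_basis <- function(x, knots) {
  if (!all(is.finite(x))) stop("all x must be finite")
  knots <- as.numeric(knots)
  if (length(knots) < 3L || any(diff(knots) <= 0))
    stop("knots must be strictly increasing with length >= 3")
  m <- rcs_raw_matrix(x, knots)
  structure(m,
            x = as.numeric(x), knots = knots, meta = "raw",
            keep = seq_len(ncol(m)),
            detrend_coef = NULL, ref_offset = NULL, ref_x = NULL,
            class = c("rcs_basis", class(m)))
}

# The raw restricted truncated-power construction.  For interior index m,
#   c_m(x) = [ (x-t_m)+^3
#              - (x-t_{k-1})+^3 (t_k - t_m)/(t_k - t_{k-1})
#              + (x-t_k)+^3 (t_{k-1} - t_m)/(t_k - t_{k-1}) ] / (t_k - t_1)^2
# which cancels the x^2 and x^3 terms beyond t_k (tail restriction).
rcs_raw_matrix <- function(x, knots) {
  k <- length(knots)
  tk <- knots[k]; tk1 <- knots[k - 1L]
  scl <- (knots[k] - knots[1L])^2
  pp <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2L), function(m) {
    tm <- knots[m]
    (pp(x - tm) -
       pp(x - tk1) * (tk - tm) / (tk - tk1) +
       pp(x - tk) * (tk1 - tm) / (tk - tk1)) / scl
  })
  m <- cbind(x, do.call(cbind, cols))
  colnames(m) <- c("lin", paste0("cub", seq_len(k - 2L)))
  m
}

# Re-create an rcs_basis object carrying over bookkeeping attributes.
rebuild_basis <- function(values, template, meta,
                          detrend_coef = attr(template, "detrend_coef"),
                          ref_offset = attr(template, "ref_offset"),
                          ref_x = attr(template, "ref_x"),
                          x = attr(template, "x"),
                          keep = attr(template, "keep")) {
  structure(values,
            x = x, knots = attr(template, "knots"), meta = meta,
            keep = keep,
            detrend_coef = detrend_coef, ref_offset = ref_offset,
            ref_x = ref_x,
            class = c("rcs_basis", "matrix", "array"))
}

#' Keep a subset of basis columns
#'
#' Restricts an (untransformed) basis to a subset of its columns — e.g.
#' drop the linear term to keep curvature columns only — while preserving
#' the ability to re-evaluate the restricted basis on new grids.
#'
#' @param basis a raw `rcs_basis`.
#' @param cols integer indices of columns to keep.
#' @return an `rcs_basis` with the selected columns.
#' @export
basis_subset <- function(basis, cols) {
  stopifnot(inherits(basis, "rcs_basis"),
            identical(attr(basis, "meta"), "raw"))
  v <- unclass_matrix(basis)[, cols, drop = FALSE]
  rebuild_basis(v, basis, meta = "raw",
                keep = attr(basis, "keep")[cols])
}

#' Remove level and linear trend from a spline basis
#'
#' Projects every column of the basis onto the orthogonal complement of
#' span{1, x} (ordinary, optionally weighted, inner product), so the
#' detrended block carries no level and no slope in `x`. This is the
#' identifiability device for the period block of an age-period-cohort
#' model: the secular trend must live elsewhere (in the drift term).
#'
#' The fitted intercept/slope pair of each column is stored so that the
#' detrended basis functions extend to new `x` via [eval_basis()].
#'
#' @param basis an `rcs_basis` object.
#' @param weights optional non-negative projection weights.
#' @return an `rcs_basis` with `meta = "detrended"`; every column is
#'   orthogonal to the constant and to `x`.
#' @export
detrend <- function(basis, weights = NULL) {
  stopifnot(inherits(basis, "rcs_basis"))
  x <- attr(basis, "x")
  v <- unclass_matrix(basis)
  Z <- cbind(1, x)
  project <- function(y) {
    fit <- if (is.null(weights)) stats::lm.fit(Z, y)
           else stats::lm.wfit(Z, y, w = weights)
    fit$coefficients
  }
  # two projection passes (iterative refinement): x on the calendar-year
  # scale amplifies rounding in a single least-squares pass
  co <- project(v)
  res <- v - Z %*% co
  co2 <- project(res)
  co <- co + co2
  res <- res - Z %*% co2
  # a column that was exactly a + b*x collapses to zero: not a basis column
  nrm0 <- sqrt(colSums(v^2))
  nrm1 <- sqrt(colSums(res^2))
  dead <- nrm1 < 1e-8 * pmax(nrm0, 1)
  if (any(dead))
    stop("detrend: rank collapse, column(s) ",
         paste(colnames(v)[dead], collapse = ", "),
         " lie in span{1, x}")
  colnames(res) <- colnames(v)
  prev <- attr(basis, "detrend_coef")
  if (!is.null(prev)) co <- prev + co   # compose with an earlier detrend
  rebuild_basis(res, basis, meta = "detrended", detrend_coef = co)
}

#' Anchor a spline basis at a reference point
#'
#' Shifts each basis column by a constant so that its (interpolated) value
#' at `x_ref` is exactly zero. Any linear combination of the anchored
#' columns then evaluates to 0 at the reference point, which is how the
#' cohort rate-ratio curve is pinned to RR = 1 at the reference cohort.
#'
#' @param basis an `rcs_basis` object (raw or detrended).
#' @param x_ref reference point, inside `[min(x), max(x)]` of the basis.
#' @return an `rcs_basis` with `meta = "referenced"`.
#' @export
set_reference <- function(basis, x_ref) {
  stopifnot(inherits(basis, "rcs_basis"), length(x_ref) == 1L,
            is.finite(x_ref))
  x <- attr(basis, "x")
  if (x_ref < min(x) || x_ref > max(x))
    stop("x_ref = ", x_ref, " outside the data range [",
         min(x), ", ", max(x), "]")
  row_ref <- eval_basis_core(basis, x_ref, apply_ref = FALSE)
  prev <- attr(basis, "ref_offset")
  off <- if (is.null(prev)) drop(row_ref) else drop(row_ref)
  v <- sweep(unclass_matrix(basis), 2L, off_total(basis, off), "-")
  colnames(v) <- colnames(basis)
  rebuild_basis(v, basis, meta = "referenced",
                ref_offset = off_store(basis, off), ref_x = x_ref)
}

# the offset to subtract from current values / to store, accounting for a
# previously applied reference (idempotence: second application subtracts 0)
off_total <- function(basis, off_new) {
  prev <- attr(basis, "ref_offset")
  if (is.null(prev)) off_new else off_new - prev
}
off_store <- function(basis, off_new) off_new

#' Evaluate basis functions on a new grid
#'
#' Re-evaluates the spline basis functions represented by an `rcs_basis`
#' object — including any detrending and reference anchoring baked into it
#' — at arbitrary points. This is what effect-curve extraction uses to get
#' basis rows on a plotting grid consistent with the fitted design.
#'
#' @param basis an `rcs_basis` object.
#' @param newx numeric points to evaluate at.
#' @return numeric matrix with `length(newx)` rows.
#' @export
eval_basis <- function(basis, newx) {
  stopifnot(inherits(basis, "rcs_basis"), all(is.finite(newx)))
  eval_basis_core(basis, newx, apply_ref = TRUE)
}

eval_basis_core <- function(basis, newx, apply_ref = TRUE) {
  m <- rcs_raw_matrix(newx, attr(basis, "knots"))
  m <- m[, attr(basis, "keep"), drop = FALSE]
  co <- attr(basis, "detrend_coef")
  if (!is.null(co)) m <- m - cbind(1, newx) %*% co
  off <- attr(basis, "ref_offset")
  if (apply_ref && !is.null(off)) {
    m <- sweep(m, 2L, off, "-")
    # evaluation exactly at the anchor returns exact zeros, so anchored
    # linear combinations (log rate ratios) are exactly 0 there
    m[newx == attr(basis, "ref_x"), ] <- 0
  }
  colnames(m) <- colnames(basis)
  m
}

unclass_matrix <- function(b) {
  v <- unclass(b)
  attributes(v) <- list(dim = dim(b), dimnames = dimnames(b))
  v
}

#' @export
print.rcs_basis <- function(x, ...) {
  cat(sprintf("Restricted cubic spline basis: %d points x %d columns (%s)\n",
              nrow(x), ncol(x), attr(x, "meta")))
  cat("knots:", paste(signif(attr(x, "knots"), 6), collapse = ", "), "\n")
  invisible(x)
}
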