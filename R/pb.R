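#' Penalized B-spline specification
#'
#' Settings of the P-spline smooths used in the GAMLSS predictors:
#' a cubic B-spline basis over equally spaced knots spanning the data range
#' with a difference penalty on adjacent coefficients.
#'
#' @param n_interior_knots number of equally spaced interior knots
#'   (default 20).
#' @param degree B-spline degree (default 3, cubic).
#' @param penalty_order order of the difference penalty (default 2: the
#'   penalty null space is the linear functions, so infinite smoothing
#'   collapses the term to a straight line).
#' @param lambda smoothing weight: a nonnegative number, `Inf` (force the
#'   term linear), or `"auto"` for local maximum-likelihood selection
#'   during fitting.
#' @return list of class `pb_spec`.
#' @export
pb_spec <- function(n_interior_knots = 20, degree = 3, penalty_order = 2,
                    lambda = "auto") {
  if (n_interior_knots < penalty_order) {
    abort("need at least `penalty_order` interior knots.")
  }
  if (degree < 1) abort("`degree` must be at least 1.")
  if (is.numeric(lambda) && any(lambda < 0)) {
    abort("`lambda` must be nonnegative.")
  }
  structure(list(n_interior_knots = n_interior_knots, degree = degree,
                 penalty_order = penalty_order, lambda = lambda),
            class = "pb_spec")
}

#' Penalized B-spline basis and penalty
#'
#' Builds the B-spline design matrix over equally spaced knots spanning
#' `[min(x), max(x)]` and the difference penalty `t(D) %*% D` on the basis
#' coefficients. The basis has `n_interior_knots + degree + 1` columns and
#' forms a partition of unity on the data range.
#'
#' @param x numeric covariate with at least 2 distinct finite values.
#' @param spec a [pb_spec()].
#' @return list of class `pb_basis`: `B` (design matrix), `P` (penalty
#'   matrix), `knots` (full knot vector), `degree`, `range` (data range).
#' @examples
#' b <- pb_basis(runif(50), pb_spec(n_interior_knots = 5))
#' range(rowSums(b$B))  # partition of unity
#' @export
pb_basis <- function(x, spec = pb_spec()) {
  if (any(!is.finite(x))) abort("`x` must be finite.")
  rng <- range(x)
  if (diff(rng) == 0) abort("`x` must contain at least 2 distinct values.")
  k <- spec$n_interior_knots
  d <- spec$degree
  h <- diff(rng) / (k + 1)
  knots <- rng[1] + h * seq(-d, k + 1 + d)
  knots[d + 1] <- rng[1]        # exact boundaries so the data range is
  knots[k + d + 2] <- rng[2]    # inside the spline support

  B <- splines::splineDesign(knots, x, ord = spec$degree + 1,
                             outer.ok = FALSE)
  nb <- ncol(B)   # k + degree + 1
  D <- diff(diag(nb), differences = spec$penalty_order)
  structure(list(B = B, P = crossprod(D), knots = knots,
                 degree = spec$degree, range = rng,
                 penalty_order = spec$penalty_order),
            class = "pb_basis")
}

# evaluate an existing basis at new covariate values (clamped evaluation is
# NOT done here; callers enforce their extrapolation policy)
pb_eval <- function(basis, x) {
  splines::splineDesign(basis$knots, x, ord = basis$degree + 1,
                        outer.ok = TRUE)
}
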