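# M-spline / I-spline basis for the baseline hazard.
# M-splines are nonnegative and integrate to one over the boundary
# interval, so nonnegative weight combinations are valid hazards and the
# corresponding I-splines give the cumulative baseline hazard.

#' Construct an M-spline basis
#'
#' @param degree Polynomial degree (3 = cubic, the default).
#' @param boundary Length-2 numeric, support of the baseline hazard.
#' @param df Number of basis functions; `df - degree - 1` interior knots
#'   are placed (at `interior_knots` if given, else equally spaced in the
#'   interior).
#' @param interior_knots Optional interior knot locations.
#' @return Object of class `mspline_basis`.
#' @export
mspline_basis <- function(degree = 3, boundary = c(0, 30), df = 5,
                          interior_knots = NULL) {
  if (df < degree + 1) stop("df must be at least degree + 1")
  n_int <- df - degree - 1
  if (is.null(interior_knots)) {
    interior_knots <- if (n_int > 0)
      seq(boundary[1], boundary[2], length.out = n_int + 2)[-c(1, n_int + 2)]
    else numeric(0)
  }
  if (length(interior_knots) != n_int)
    stop("need exactly df - degree - 1 interior knots")
  interior_knots <- sort(interior_knots)
  if (length(interior_knots) && (min(interior_knots) <= boundary[1] ||
                                 max(interior_knots) >= boundary[2]))
    stop("interior knots must lie strictly inside the boundary")
  ord <- degree + 1
  knots <- c(rep(boundary[1], ord), interior_knots, rep(boundary[2], ord))
  structure(list(degree = degree, order = ord, boundary = boundary,
                 interior = interior_knots, knots = knots, df = df),
            class = "mspline_basis")
}

#' Evaluate the M-spline basis
#'
#' `M_i(t) = order * B_i(t) / (k_{i+order} - k_i)` from the B-spline
#' basis, so each column is nonnegative and integrates to one.
#'
#' @param basis An [mspline_basis()].
#' @param t Evaluation points within the boundary interval.
#' @return Matrix `length(t) x df`.
#' @export
mspline_eval <- function(basis, t) {
  if (any(t < basis$boundary[1] - 1e-12 | t > basis$boundary[2] + 1e-12))
    stop("t outside the boundary knots")
  t <- pmin(pmax(t, basis$boundary[1]), basis$boundary[2])
  # splineDesign is right-open at the last knot; nudge the endpoint in
  tb <- pmin(t, basis$boundary[2] - 1e-9 * diff(basis$boundary))
  B <- splines::splineDesign(basis$knots, tb, ord = basis$order)
  denom <- basis$knots[seq_len(basis$df) + basis$order] -
    basis$knots[seq_len(basis$df)]
  sweep(B, 2, basis$order / denom, `*`)
}

#' Evaluate the I-spline (integrated M-spline) basis
#'
#' Exact integration of the piecewise-polynomial M-splines from the left
#' boundary to each `t` by per-piece Gauss-Legendre quadrature (exact for
#' the cubic default).  Columns run from 0 at the left boundary to 1 at
#' the right boundary.
#'
#' @inheritParams mspline_eval
#' @return Matrix `length(t) x df`.
#' @export
ispline_eval <- function(basis, t) {
  if (any(t < basis$boundary[1] - 1e-12 | t > basis$boundary[2] + 1e-12))
    stop("t outside the boundary knots")
  t <- pmin(pmax(t, basis$boundary[1]), basis$boundary[2])
  # 7-point Gauss-Legendre nodes/weights on [-1, 1]
  gn <- c(-0.9491079123427585, -0.7415311855993945, -0.4058451513773972, 0,
          0.4058451513773972, 0.7415311855993945, 0.9491079123427585)
  gw <- c(0.1294849661688697, 0.2797053914892766, 0.3818300505051189,
          0.4179591836734694, 0.3818300505051189, 0.2797053914892766,
          0.1294849661688697)
  brk <- unique(c(basis$boundary[1], basis$interior, basis$boundary[2]))
  out <- matrix(0, length(t), basis$df)
  for (i in seq_along(t)) {
    ti <- t[i]
    acc <- numeric(basis$df)
    for (s in seq_len(length(brk) - 1)) {
      a <- brk[s]; b <- min(brk[s + 1], ti)
      if (b <= a) break
      x <- (a + b) / 2 + (b - a) / 2 * gn
      acc <- acc + colSums(mspline_eval(basis, x) * gw) * (b - a) / 2
    }
    out[i, ] <- acc
  }
  out
}

#' Orthogonal polynomial basis with a reusable projection record
#'
#' Thin wrapper around [stats::poly()] retaining the centring/QR record,
#' so the same basis can be evaluated at new covariate values for
#' prediction curves.
#'
#' @param x Numeric covariate with at least `degree + 1` distinct values.
#' @param degree Polynomial degree (default 2).
#' @return List `basis` (matrix with orthonormal-style columns) and
#'   `record` (the `coefs` needed to re-evaluate).
#' @export
orthogonal_poly <- function(x, degree = 2) {
  if (length(unique(x)) < degree + 1)
    stop("fewer distinct values than degree + 1")
  b <- stats::poly(x, degree = degree)
  list(basis = unclass(b)[, , drop = FALSE], record = attr(b, "coefs"))
}

#' Evaluate a stored orthogonal-polynomial basis at new values
#'
#' @param record The `record` from [orthogonal_poly()].
#' @param newx New covariate values.
#' @param degree Degree used to build the record.
#' @return Basis matrix at `newx`.
#' @export
orthogonal_poly_predict <- function(record, newx, degree = 2) {
  unclass(stats::poly(newx, degree = degree, coefs = record))[, , drop = FALSE]
}
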