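#' B-spline basis specification
#'
#' Defines the B-spline basis used for every time-varying coefficient in a
#' model: the number of basis functions, the polynomial degree and the domain
#' of the effect modifier (calendar time). Knots are equally spaced over the
#' domain, with `degree` additional knots extended beyond each boundary so that
#' exactly `n_basis` basis functions are defined — the standard P-spline
#' construction, where a deliberately rich basis is regularized by a difference
#' penalty rather than by knot placement.
#'
#' @param n_basis Number of B-spline basis functions (default 55, one per
#'   observed month in a 2008-2012 monthly surveillance series).
#' @param degree Polynomial degree of the B-splines (default 3, cubic).
#' @param domain Numeric length-2 vector, the closed interval of valid
#'   modifier values.
#' @return An object of class `"basis_spec"`: a list with elements `n_basis`,
#'   `degree`, `domain` and the full extended `knots` vector.
#' @examples
#' sp <- basis_spec(n_basis = 10, degree = 3, domain = c(1, 55))
#' B <- bspline_basis(seq(1, 55, length.out = 7), sp)
#' rowSums(B)  # partition of unity
#' @export
basis_spec <- function(n_basis = 55L, degree = 3L, domain = c(1, 55)) {
  n_basis <- as.integer(n_basis)
  degree <- as.integer(degree)
  if (length(domain) != 2L || !is.numeric(domain) || any(!is.finite(domain)))
    stop("`domain` must be a finite numeric interval [t_min, t_max]")
  if (domain[2] <= domain[1])
    stop("`domain` is degenerate: t_max must exceed t_min")
  if (degree < 0L) stop("`degree` must be nonnegative")
  if (n_basis <= degree)
    stop("`n_basis` must exceed `degree` (got n_basis = ", n_basis,
         ", degree = ", degree, ")")
  # equally spaced knots; n_basis - degree interior intervals, degree-extended
  # boundary knots => exactly n_basis basis functions of the given degree
  dx <- diff(domain) / (n_basis - degree)
  knots <- domain[1] + dx * seq.int(-degree, n_basis)
  # pin the boundary knots to the domain exactly (guards rounding at t_max)
  knots[degree + 1L] <- domain[1]
  knots[n_basis + 1L] <- domain[2]
  structure(
    list(n_basis = n_basis, degree = degree, domain = as.numeric(domain),
         knots = knots),
    class = "basis_spec"
  )
}

#' @export
print.basis_spec <- function(x, ...) {
  cat(sprintf("B-spline basis: %d functions of degree %d on [%g, %g]\n",
              x$n_basis, x$degree, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Evaluate a B-spline basis
#'
#' Evaluates all basis functions of a [basis_spec()] at a vector of modifier
#' values, returning the n-by-`n_basis` design matrix used for a single smooth
#' term. Rows sum to one (partition of unity) and each basis function has local
#' support over `degree + 1` knot intervals. The right domain boundary is a
#' valid input (the last interval is treated as closed).
#'
#' @param t_values Numeric vector of modifier (time) values, all inside
#'   `spec$domain`.
#' @param spec A [basis_spec()].
#' @param sparse Return a sparse `Matrix::dgCMatrix` (default `FALSE`).
#' @return Matrix with `length(t_values)` rows and `spec$n_basis` columns,
#'   columns ordered left to right by support.
#' @export
bspline_basis <- function(t_values, spec, sparse = FALSE) {
  stopifnot(inherits(spec, "basis_spec"))
  t_values <- as.numeric(t_values)
  bad <- !is.finite(t_values) | t_values < spec$domain[1] |
    t_values > spec$domain[2]
  if (any(bad))
    stop("modifier value(s) outside basis domain [", spec$domain[1], ", ",
         spec$domain[2], "]: ",
         paste(utils::head(t_values[bad], 5L), collapse = ", "))
  B <- splines::splineDesign(spec$knots, t_values, ord = spec$degree + 1L,
                             outer.ok = FALSE, sparse = sparse)
  dimnames(B) <- NULL
  B
}

#' Difference penalty matrix
#'
#' Builds the matrix that applies d-th order finite differences to adjacent
#' B-spline coefficients. The P-spline roughness penalty for a smooth with
#' coefficients `gamma` is `lambda * || difference_matrix(k, d) %*% gamma ||^2`;
#' its null space is exactly the polynomial sequences of degree `< d`, so heavy
#' penalization shrinks a smooth towards a degree-(d-1) polynomial in time.
#'
#' @param n_basis Number of basis coefficients.
#' @param order Difference order d (`1 <= order < n_basis`); the default
#'   analysis uses 2.
#' @return A `(n_basis - order)` by `n_basis` matrix of full row rank.
#' @examples
#' difference_matrix(4, 2)
#' @export
difference_matrix <- function(n_basis, order = 2L) {
  n_basis <- as.integer(n_basis)
  order <- as.integer(order)
  if (order < 1L) stop("difference `order` must be at least 1")
  if (order >= n_basis)
    stop("invalid penalty: difference order (", order,
         ") must be smaller than the basis dimension (", n_basis, ")")
  diff(diag(n_basis), differences = order)
}
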