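#' Predetermined basis systems on [0, 1]
#'
#' Constructs a clamped B-spline basis system on the unit interval with
#' uniformly spaced interior knots. The basis is "predetermined" in the sense
#' of functional data analysis: its knots and order are fixed before fitting,
#' and only the coefficients multiplying the basis functions are estimated.
#' `order = 1` yields indicator functions of equal subintervals and
#' `order = 2` the piecewise-linear hat functions, so the same constructor
#' covers the piecewise-constant and linear systems used by degenerate layers.
#'
#' @param order polynomial order of the B-splines (order 5 = degree 4;
#'   the convention used throughout functional data analysis).
#' @param n_basis number of basis functions J; must satisfy
#'   `n_basis >= order`.
#' @return An object of class `basis_system` with fields `kind`, `order`,
#'   `n_basis` and the full (clamped) `knots` vector.
#' @examples
#' bs <- bspline_system(order = 5, n_basis = 7)
#' B <- eval_basis(bs, seq(0, 1, length.out = 11))
#' rowSums(B) # partition of unity: all 1
#' @export
bspline_system <- function(order, n_basis) {
  order <- as.integer(order)
  n_basis <- as.integer(n_basis)
  if (length(order) != 1L || is.na(order) || order < 1L)
    stop("'order' must be a positive integer")
  if (length(n_basis) != 1L || is.na(n_basis) || n_basis < order)
    stop("invalid basis configuration: need n_basis >= order >= 1 (got order = ",
         order, ", n_basis = ", n_basis, ")")
  n_interior <- n_basis - order
  interior <- if (n_interior > 0L) {
    seq(0, 1, length.out = n_interior + 2L)[-c(1L, n_interior + 2L)]
  } else {
    numeric(0)
  }
  structure(
    list(kind = "bspline", order = order, n_basis = n_basis,
         knots = c(rep(0, order), interior, rep(1, order)),
         domain = c(0, 1)),
    class = "basis_system"
  )
}

#' @export
print.basis_system <- function(x, ...) {
  cat(sprintf("B-spline basis system: order %d, %d basis functions on [0, 1]\n",
              x$order, x$n_basis))
  invisible(x)
}

#' Evaluate a basis system at points in [0, 1]
#'
#' @param sys a `basis_system`.
#' @param points numeric vector with all entries in `[0, 1]`.
#' @return A `length(points) x n_basis` matrix with entry (i, j) equal to the
#'   j-th basis function evaluated at `points[i]`.
#' @export
eval_basis <- function(sys, points) {
  stopifnot(inherits(sys, "basis_system"))
  points <- as.numeric(points)
  if (any(!is.finite(points)) || any(points < 0) || any(points > 1))
    stop("basis evaluation points must lie in [0, 1]")
  B <- splines::splineDesign(sys$knots, points, ord = sys$order)
  dimnames(B) <- NULL
  B
}

#' Uniform trapezoid quadrature grid on [0, 1]
#'
#' @param size number of grid points (>= 2); endpoints 0 and 1 are included.
#' @return An object of class `quad_grid` with `points`, trapezoid `weights`
#'   (summing to 1, the length of the interval) and `size`.
#' @export
quad_grid <- function(size = 50L) {
  size <- as.integer(size)
  if (length(size) != 1L || is.na(size) || size < 2L)
    stop("'size' must be an integer >= 2")
  h <- 1 / (size - 1L)
  w <- rep(h, size)
  w[c(1L, size)] <- h / 2
  structure(list(points = seq(0, 1, length.out = size), weights = w,
                 size = size),
            class = "quad_grid")
}

#' Trapezoid-rule integral of gridded values over [0, 1]
#'
#' @param values function values on the grid points.
#' @param grid a `quad_grid`.
#' @return The composite-trapezoid approximation of the integral over [0, 1].
#' @export
quad_integrate <- function(values, grid) {
  stopifnot(inherits(grid, "quad_grid"))
  if (length(values) != grid$size)
    stop("length of 'values' (", length(values),
         ") does not match grid size (", grid$size, ")")
  sum(as.numeric(values) * grid$weights)
}
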