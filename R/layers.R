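#' Parameters of one functional network layer
#'
#' A functional layer maps a function-valued input to a function-valued
#' output through a bivariate weight surface
#' \eqn{\beta(t, s) = \sum_{\ell} \sum_j w_{\ell j}\, \eta_\ell(s)\, \eta_j(t)}
#' and a functional bias \eqn{\alpha_0(t) = \sum_j b_j\, \eta_j(t)}, followed
#' by a pointwise activation. The weight and bias are parameterized by their
#' basis coefficients; the basis systems themselves are predetermined.
#'
#' @param W `J_in x J_out` matrix of weight-surface coefficients.
#' @param b length-`J_out` vector of bias coefficients (`NULL` for layers
#'   without a functional bias, e.g. the first layer).
#' @param in_basis,out_basis [bspline_system()] objects for the s- and
#'   t-directions.
#' @param activation activation name: "tanh", "relu", "sigmoid" or
#'   "identity".
#' @return An object of class `functional_layer_params`.
#' @export
functional_layer_params <- function(W, b = NULL, in_basis, out_basis,
                                    activation = "tanh") {
  W <- as.matrix(W)
  stopifnot(inherits(in_basis, "basis_system"),
            inherits(out_basis, "basis_system"))
  if (nrow(W) != in_basis$n_basis || ncol(W) != out_basis$n_basis)
    stop("weight coefficient matrix must be J_in x J_out = ",
         in_basis$n_basis, " x ", out_basis$n_basis,
         " (got ", nrow(W), " x ", ncol(W), ")")
  if (!is.null(b)) {
    b <- as.numeric(b)
    if (length(b) != out_basis$n_basis)
      stop("bias coefficient vector must have length J_out = ",
           out_basis$n_basis)
  }
  activation_fun(activation) # validate
  structure(list(W = W, b = b, in_basis = in_basis, out_basis = out_basis,
                 activation = activation),
            class = "functional_layer_params")
}

#' Covariate block
#'
#' Scalar covariates (e.g. age, sex) and their coefficients, added to the
#' pre-activation of a subnet's first layer.
#'
#' @param X `n x q` covariate matrix.
#' @param alpha length-`q` coefficient vector.
#' @return An object of class `covariate_block`.
#' @export
covariate_block <- function(X, alpha) {
  X <- as.matrix(X)
  alpha <- as.numeric(alpha)
  if (ncol(X) != length(alpha))
    stop("covariate matrix has ", ncol(X), " columns but 'alpha' has length ",
         length(alpha))
  structure(list(X = X, alpha = alpha), class = "covariate_block")
}

#' Function-valued hidden state on a quadrature grid
#'
#' @param grid a [quad_grid()].
#' @param values `n x grid$size` matrix: row i holds sample i's hidden
#'   function evaluated at the grid points.
#' @return An object of class `hidden_function`.
#' @export
hidden_function <- function(grid, values) {
  stopifnot(inherits(grid, "quad_grid"))
  values <- as.matrix(values)
  if (ncol(values) != grid$size)
    stop("hidden-function values must have grid$size = ", grid$size,
         " columns")
  if (any(!is.finite(values))) stop("hidden-function values must be finite")
  structure(list(grid = grid, values = values), class = "hidden_function")
}

#' First functional layer: omics variant function to hidden function
#'
#' Computes \eqn{Z^{(1)}_i(t) = \sigma\big(X_i\alpha + \int G_i(s)\,
#' \beta^{(1)}(t, s)\, ds\big)} on the grid. The integral against the Dirac
#' comb is evaluated exactly via [dirac_design()]; the first layer carries no
#' functional bias.
#'
#' @param ovf a [variant_function()].
#' @param params a [functional_layer_params()]; any `b` is ignored here.
#' @param cov optional [covariate_block()].
#' @param grid a [quad_grid()] on which the output function is represented.
#' @return A [hidden_function()].
#' @export
first_layer_forward <- function(ovf, params, cov = NULL, grid = quad_grid()) {
  stopifnot(inherits(ovf, "variant_function"),
            inherits(params, "functional_layer_params"))
  Phi <- dirac_design(ovf, params$in_basis)
  E_out <- eval_basis(params$out_basis, grid$points)
  pre <- Phi %*% params$W %*% t(E_out)
  if (!is.null(cov)) {
    stopifnot(inherits(cov, "covariate_block"))
    if (nrow(cov$X) != nrow(Phi))
      stop("covariate block and modality have different sample counts")
    pre <- pre + drop(cov$X %*% cov$alpha) # recycled down columns
  }
  hidden_function(grid, activation_fun(params$activation)$f(pre))
}

#' Hidden functional layer: function to function
#'
#' Computes \eqn{Z^{(d)}_i(t) = \sigma\big(\alpha_0(t) + \int Z^{(d-1)}_i(s)
#' \,\beta(t, s)\, ds\big)} with the s-integral evaluated by trapezoid
#' quadrature on the input grid.
#'
#' @param Z_prev a [hidden_function()].
#' @param params a [functional_layer_params()] with bias coefficients `b`.
#' @return A [hidden_function()] on the same grid.
#' @export
hidden_layer_forward <- function(Z_prev, params) {
  stopifnot(inherits(Z_prev, "hidden_function"),
            inherits(params, "functional_layer_params"))
  grid <- Z_prev$grid
  E_in <- eval_basis(params$in_basis, grid$points)
  E_out <- eval_basis(params$out_basis, grid$points)
  U <- E_in * grid$weights # rows scaled by trapezoid weights
  pre <- (Z_prev$values %*% U) %*% params$W %*% t(E_out)
  if (!is.null(params$b))
    pre <- pre + rep(drop(E_out %*% params$b), each = nrow(pre))
  hidden_function(grid, activation_fun(params$activation)$f(pre))
}

#' Output functional layer: function to embedding vector
#'
#' Computes \eqn{Z^{(D)}_{iu} = f\big(b_u + \int Z^{(D-1)}_i(s)\,
#' \beta_u(s)\, ds\big)} for each of the q output units, where each
#' \eqn{\beta_u(s) = \sum_\ell w_{\ell u}\, \eta_\ell(s)}.
#'
#' @param Z_prev a [hidden_function()].
#' @param weights `J_in x q` matrix of weight-function coefficients.
#' @param biases length-`q` vector of scalar biases.
#' @param in_basis [bspline_system()] expanding the weight functions.
#' @param link link function name (default "identity").
#' @return `n x q` numeric matrix of embeddings.
#' @export
output_layer_forward <- function(Z_prev, weights, biases, in_basis,
                                 link = "identity") {
  stopifnot(inherits(Z_prev, "hidden_function"),
            inherits(in_basis, "basis_system"))
  weights <- as.matrix(weights)
  if (nrow(weights) != in_basis$n_basis)
    stop("'weights' must have J_in = ", in_basis$n_basis, " rows")
  biases <- as.numeric(biases)
  if (length(biases) != ncol(weights))
    stop("'biases' must have one entry per output unit")
  grid <- Z_prev$grid
  U <- eval_basis(in_basis, grid$points) * grid$weights
  pre <- (Z_prev$values %*% U) %*% weights
  pre <- pre + rep(biases, each = nrow(pre))
  activation_fun(link)$f(pre)
}
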