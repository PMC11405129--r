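#' Functional linear model fitted in closed form (ridge)
#'
#' The scalar-on-function (or vector-on-function) linear model
#' \eqn{y_i = \alpha_0 + X_i\alpha + \sum_k \int_0^1 G_{ki}(t)\beta_k(t)\,dt
#' + \epsilon_i}, with each functional coefficient expanded in a
#' predetermined B-spline basis. Because the omics variant functions are
#' Dirac combs, the integrals reduce exactly to basis design columns
#' ([dirac_design()]) and the model is ordinary ridge regression on the
#' design `[1 | X | Phi_1 | Phi_2 | ...]`. The objective matches the
#' networks' regularized loss, \eqn{\frac{1}{n}\|y - A\theta\|^2 +
#' \frac{\lambda}{2}\|\theta_{pen}\|^2}, with the intercept and covariate
#' columns unpenalized, so closed-form and gradient-trained fits are
#' directly comparable at the same \eqn{\lambda}.
#'
#' @param modalities list of modality objects: [variant_function()] for
#'   functional inputs, numeric matrices for scalar/multivariate inputs
#'   entering as plain columns.
#' @param y phenotype vector or `n x d` matrix.
#' @param covariates optional covariate matrix (unpenalized).
#' @param basis a [bspline_system()] shared by all functional modalities, or
#'   a list with one basis per modality.
#' @param lambda nonnegative ridge penalty.
#' @return An object of class `flm_model` with coefficient blocks and the
#'   fitting bases; supports `predict()`.
#' @export
fit_flm <- function(modalities, y, covariates = NULL,
                    basis = bspline_system(5L, 7L), lambda = 0) {
  if (inherits(modalities, "variant_function") || is.matrix(modalities))
    modalities <- list(modalities)
  y <- as.matrix(y)
  n <- nrow(y)
  bases <- if (inherits(basis, "basis_system"))
    rep(list(basis), length(modalities)) else basis
  if (length(bases) != length(modalities))
    stop("need one basis per modality (or a single shared basis)")
  blocks <- list(intercept = matrix(1, n, 1L))
  penalized <- FALSE
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n) stop("covariates and y disagree on sample count")
    blocks$covariates <- covariates
    penalized <- c(penalized, rep(FALSE, ncol(covariates)))
  }
  functional <- logical(length(modalities))
  for (k in seq_along(modalities)) {
    m <- modalities[[k]]
    if (inherits(m, "variant_function")) {
      functional[k] <- TRUE
      blk <- dirac_design(m, bases[[k]])
    } else {
      blk <- as.matrix(m)
    }
    if (nrow(blk) != n) stop("modality ", k, " and y disagree on sample count")
    blocks[[paste0("m", k)]] <- blk
    penalized <- c(penalized, rep(TRUE, ncol(blk)))
  }
  A <- do.call(cbind, blocks)
  M <- crossprod(A) + (n * lambda / 2) * diag(as.numeric(penalized))
  theta <- tryCatch(solve(M, crossprod(A, y)), error = function(e) {
    if (lambda == 0)
      stop("singular normal equations at lambda = 0; refit with lambda > 0",
           call. = FALSE)
    stop(e)
  })
  widths <- vapply(blocks, ncol, integer(1))
  ends <- cumsum(widths)
  block_idx <- Map(function(s, e) seq.int(s, e), ends - widths + 1L, ends)
  names(block_idx) <- names(blocks)
  structure(list(coefficients = theta, block_idx = block_idx,
                 bases = bases, functional = functional,
                 has_covariates = !is.null(covariates), lambda = lambda),
            class = "flm_model")
}

#' @export
print.flm_model <- function(x, ...) {
  cat(sprintf("Functional linear model: %d modalities, %d coefficients, lambda = %g\n",
              sum(grepl("^m", names(x$block_idx))), nrow(x$coefficients),
              x$lambda))
  invisible(x)
}

#' Functional coefficient curve of a fitted FLM
#'
#' Reconstructs \eqn{\beta_k(t)} of a functional modality as the basis
#' expansion of its coefficient block.
#'
#' @param model a fitted `flm_model`.
#' @param k modality index (must be a functional modality).
#' @param points evaluation points in [0, 1].
#' @return Matrix `length(points) x d` of coefficient-curve values.
#' @export
flm_beta <- function(model, k, points = seq(0, 1, length.out = 101L)) {
  stopifnot(inherits(model, "flm_model"))
  if (!model$functional[k]) stop("modality ", k, " is not functional")
  idx <- model$block_idx[[paste0("m", k)]]
  eval_basis(model$bases[[k]], points) %*%
    model$coefficients[idx, , drop = FALSE]
}

#' Predict from a fitted functional linear model
#'
#' @param object a fitted `flm_model`.
#' @param modalities list of modality objects as in [fit_flm()].
#' @param covariates optional covariate matrix.
#' @param ... unused.
#' @return `n x d` matrix of predictions.
#' @export
predict.flm_model <- function(object, modalities, covariates = NULL, ...) {
  if (inherits(modalities, "variant_function") || is.matrix(modalities))
    modalities <- list(modalities)
  n <- nrow(as.matrix(if (inherits(modalities[[1L]], "variant_function"))
    modalities[[1L]]$values else modalities[[1L]]))
  blocks <- list(matrix(1, n, 1L))
  if (object$has_covariates) {
    if (is.null(covariates)) stop("model was fitted with covariates")
    blocks <- c(blocks, list(as.matrix(covariates)))
  }
  for (k in seq_along(modalities)) {
    m <- modalities[[k]]
    blocks <- c(blocks, list(
      if (object$functional[k]) dirac_design(m, object$bases[[k]])
      else as.matrix(m)))
  }
  do.call(cbind, blocks) %*% object$coefficients
}

#' Plain feedforward neural network on concatenated raw inputs
#'
#' The non-functional deep-learning baseline: all modality matrices are
#' concatenated column-wise and fed to a dense network trained with the same
#' regularized loss and ADADELTA stack as the multimodal model.
#'
#' @param X `n x p` input matrix (concatenate modalities beforehand, e.g.
#'   with `cbind`).
#' @param y phenotype vector or matrix.
#' @param widths hidden-layer widths.
#' @param lambda L2 penalty.
#' @param schedule a [fit_schedule()].
#' @param seed initialization seed.
#' @param activation hidden activation.
#' @param normalize_inputs,standardize_response see [fit_mfdl()].
#' @return An object of class `nn_model` with the trained network and its
#'   training history; supports `predict()`.
#' @export
fit_nn <- function(X, y, widths = c(16L, 8L), lambda = 0,
                   schedule = fit_schedule(), seed = 1L,
                   activation = "tanh", normalize_inputs = FALSE,
                   standardize_response = FALSE) {
  X <- as.matrix(X); y <- as.matrix(y)
  model <- build_mfdl(
    list(subnet_config("identity", p = ncol(X))),
    head_config(hidden_widths = widths, output_dim = ncol(y),
                activation = activation),
    seed = seed)
  fit <- fit_mfdl(model, list(X), y, lambda = lambda, schedule = schedule,
                  normalize_inputs = normalize_inputs,
                  standardize_response = standardize_response)
  structure(list(model = fit$model, history = fit$history, lambda = lambda),
            class = "nn_model")
}

#' @export
predict.nn_model <- function(object, modalities, covariates = NULL, ...) {
  if (is.list(modalities) && !is.matrix(modalities))
    modalities <- do.call(cbind, lapply(modalities, function(m)
      if (inherits(m, "variant_function")) m$values else as.matrix(m)))
  mfdl_forward(object$model, list(as.matrix(modalities)))
}

# Concatenate all modality value matrices column-wise onto one artificial
# [0, 1] axis with uniform pseudo-positions.
concat_pseudo_modality <- function(modalities) {
  vals <- do.call(cbind, lapply(modalities, function(m)
    if (inherits(m, "variant_function")) m$values else as.matrix(m)))
  variant_function(vals, positions_bp = seq_len(ncol(vals)),
                   modality_id = "concatenated")
}

#' Single functional network with three hidden layers (FNN-3HL)
#'
#' The strongest non-multimodal baseline: all inputs are concatenated
#' column-wise onto one artificial [0, 1] axis with uniform pseudo-positions
#' and modelled by a single functional network with three activation-bearing
#' hidden layers (one first functional layer, two function-to-function
#' layers) followed by a linear function-to-vector output layer.
#'
#' @param modalities list of modality objects to concatenate.
#' @param y phenotype vector or matrix.
#' @param lambda L2 penalty.
#' @param schedule a [fit_schedule()].
#' @param seed initialization seed.
#' @param n_basis,order,grid_size basis configuration of the functional
#'   layers.
#' @param activation hidden activation.
#' @param normalize_inputs,standardize_response see [fit_mfdl()].
#' @return An object of class `fnn3hl_model`; supports `predict()`.
#' @export
fit_fnn3hl <- function(modalities, y, lambda = 0, schedule = fit_schedule(),
                       seed = 1L, n_basis = 7L, order = 5L, grid_size = 50L,
                       activation = "tanh", normalize_inputs = FALSE,
                       standardize_response = FALSE) {
  if (inherits(modalities, "variant_function") || is.matrix(modalities))
    modalities <- list(modalities)
  y <- as.matrix(y)
  pseudo <- concat_pseudo_modality(modalities)
  model <- build_mfdl(
    list(subnet_config("functional", n_hidden = 2L, order = order,
                       n_basis = n_basis, grid_size = grid_size,
                       embedding_width = ncol(y), activation = activation)),
    head_cfg = NULL, seed = seed)
  fit <- fit_mfdl(model, list(pseudo), y, lambda = lambda,
                  schedule = schedule,
                  normalize_inputs = normalize_inputs,
                  standardize_response = standardize_response)
  structure(list(model = fit$model, history = fit$history, lambda = lambda),
            class = "fnn3hl_model")
}

#' @export
predict.fnn3hl_model <- function(object, modalities, covariates = NULL, ...) {
  if (inherits(modalities, "variant_function") || is.matrix(modalities))
    modalities <- list(modalities)
  mfdl_forward(object$model, list(concat_pseudo_modality(modalities)))
}
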