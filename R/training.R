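#' Regularized training loss
#'
#' The empirical risk is \eqn{J = \frac{1}{n}\sum_i \|y_i - \hat y_i\|^2};
#' the regularized loss adds an L2 penalty on the weight arrays only,
#' \eqn{\tilde J = J + \frac{\lambda}{2}\|W\|_2^2}. Biases and covariate
#' coefficients are excluded from the penalty.
#'
#' @param y,y_hat `n x d` matrices (or length-n vectors) of observed and
#'   fitted phenotypes.
#' @param model optional `mfdl_model` whose weights enter the penalty.
#' @param lambda nonnegative penalty parameter.
#' @return List with components `J` and `J_tilde`.
#' @export
mfdl_loss <- function(y, y_hat, model = NULL, lambda = 0) {
  y <- as.matrix(y); y_hat <- as.matrix(y_hat)
  if (!identical(dim(y), dim(y_hat)))
    stop("'y' and 'y_hat' must have identical dimensions")
  if (lambda < 0) stop("'lambda' must be nonnegative")
  J <- sum((y - y_hat)^2) / nrow(y)
  pen <- if (is.null(model) || lambda == 0) 0 else
    lambda / 2 * penalty_sq_norm(collect_params(model))
  list(J = J, J_tilde = J + pen)
}

# Forward + reverse pass on prepared inputs; returns the loss pieces and the
# exact gradient of J_tilde for every parameter of the discretized network.
grad_core <- function(model, inputs, X, Y, lambda) {
  fw <- forward_core(model, inputs, X = X, keep = TRUE)
  n <- nrow(Y)
  resid <- fw$y_hat - Y
  J <- sum(resid^2) / n
  dY <- (2 / n) * resid
  grads <- list()
  if (is.null(model$head)) {
    dZwide <- dY
  } else {
    bk <- layers_backward(model$head$layers, fw$head_caches, dY)
    for (d in seq_along(bk$grads))
      for (nm in names(bk$grads[[d]]))
        grads[[sprintf("head.l%d.%s", d, nm)]] <- bk$grads[[d]][[nm]]
    dZwide <- bk$dA
  }
  col0 <- 0L
  for (k in seq_along(model$subnets)) {
    q <- model$subnets[[k]]$config$embedding_width
    dEmb <- dZwide[, col0 + seq_len(q), drop = FALSE]
    col0 <- col0 + q
    if (model$subnets[[k]]$config$kind == "identity") next
    bk <- layers_backward(model$subnets[[k]]$layers, fw$sub_caches[[k]], dEmb)
    for (d in seq_along(bk$grads))
      for (nm in names(bk$grads[[d]]))
        grads[[sprintf("s%d.l%d.%s", k, d, nm)]] <- bk$grads[[d]][[nm]]
  }
  J_tilde <- J
  if (lambda > 0) {
    flat <- collect_params(model)
    J_tilde <- J + lambda / 2 * penalty_sq_norm(flat)
    for (nm in names(grads)) {
      if (is_penalized(nm)) grads[[nm]] <- grads[[nm]] + lambda * flat[[nm]]
    }
  }
  # order gradients like collect_params for downstream consumers
  flat_names <- names(collect_params(model))
  list(grads = grads[flat_names], J = J, J_tilde = J_tilde, y_hat = fw$y_hat)
}

#' Exact gradients of the regularized loss
#'
#' Reverse-mode differentiation of the discretized forward pass: basis
#' evaluations and quadrature weights are constants, so the gradient is the
#' exact derivative of the objective actually minimized. The penalty
#' contributes \eqn{\lambda W} to weight gradients and nothing to biases.
#'
#' @inheritParams mfdl_forward
#' @param y `n x d` phenotype matrix (or length-n vector).
#' @param lambda nonnegative penalty parameter.
#' @return Named list of gradient arrays, one per parameter, in the same
#'   order and shapes as the model's parameter list.
#' @export
mfdl_gradients <- function(model, modalities, y, covariates = NULL,
                           lambda = 0) {
  stopifnot(inherits(model, "mfdl_model"))
  inputs <- prepare_inputs(model, modalities)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  y <- as.matrix(y)
  if (nrow(y) != nrow(inputs[[1L]]))
    stop("'y' and the modalities disagree on sample count")
  if (!is.null(model$norm$y)) y <- apply_norm(y, model$norm$y)
  grad_core(model, inputs, covariates, y, lambda)$grads
}

#' ADADELTA optimizer state
#'
#' Per-parameter decaying accumulators of squared gradients and squared
#' updates; the effective step size is
#' \eqn{\Delta = -\sqrt{E[\Delta^2] + \epsilon} / \sqrt{E[g^2] + \epsilon}
#' \cdot g}, so no global learning rate is tuned.
#'
#' @param params named list of parameter arrays (as from a model).
#' @param rho decay rate of the accumulators, in (0, 1).
#' @param eps small positive constant for numerical conditioning.
#' @return An object of class `adadelta_state`.
#' @export
adadelta_init <- function(params, rho = 0.95, eps = 1e-6) {
  stopifnot(rho > 0, rho < 1, eps > 0)
  zeros <- lapply(params, function(p) p * 0)
  structure(list(rho = rho, eps = eps, acc_grad_sq = zeros,
                 acc_update_sq = zeros),
            class = "adadelta_state")
}

#' One ADADELTA update of every parameter
#'
#' @param state an [adadelta_init()] state.
#' @param params named list of parameter arrays.
#' @param grads named list of gradient arrays with matching shapes.
#' @return List with updated `params` and `state`.
#' @export
adadelta_step <- function(state, params, grads) {
  stopifnot(inherits(state, "adadelta_state"))
  rho <- state$rho; eps <- state$eps
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) stop("missing gradient for parameter '", nm, "'")
    Eg <- rho * state$acc_grad_sq[[nm]] + (1 - rho) * g^2
    delta <- -sqrt(state$acc_update_sq[[nm]] + eps) / sqrt(Eg + eps) * g
    state$acc_grad_sq[[nm]] <- Eg
    state$acc_update_sq[[nm]] <- rho * state$acc_update_sq[[nm]] +
      (1 - rho) * delta^2
    params[[nm]] <- params[[nm]] + delta
  }
  list(params = params, state = state)
}

#' Training schedule
#'
#' @param max_epochs maximum number of full-batch epochs.
#' @param tol relative change in the regularized loss below which training is
#'   considered converged.
#' @param patience number of epochs over which the relative change is
#'   measured.
#' @return An object of class `fit_schedule`.
#' @export
fit_schedule <- function(max_epochs = 2000L, tol = 1e-6, patience = 50L) {
  structure(list(max_epochs = as.integer(max_epochs), tol = tol,
                 patience = as.integer(patience)),
            class = "fit_schedule")
}

#' Fit a model by full-batch gradient descent with ADADELTA steps
#'
#' Repeats forward pass, exact backpropagation and an ADADELTA parameter
#' update on the full training batch until the relative improvement of the
#' regularized loss over `patience` epochs falls below `tol`, or
#' `max_epochs` is reached. Fully deterministic given the model (whose
#' initialization seed is fixed at build time) and the data.
#'
#' Optionally, subnet inputs (the Dirac design or raw matrices) and the
#' response can be column-standardized from the training batch
#' (`normalize_inputs`, `standardize_response`). The normalization constants
#' are stored on the returned model, so [mfdl_forward()] and `predict()`
#' transparently map back to the original phenotype scale; the training
#' history is reported on the scale of the objective actually minimized.
#'
#' @inheritParams mfdl_gradients
#' @param schedule a [fit_schedule()].
#' @param rho,eps ADADELTA hyperparameters.
#' @param normalize_inputs standardize every subnet input column from the
#'   training batch before optimizing.
#' @param standardize_response standardize phenotype columns before
#'   optimizing (predictions are back-transformed).
#' @return List with the trained `model` (the iterate attaining the smallest
#'   regularized loss along the path; ADADELTA is not strictly monotone), a
#'   `history` data frame (epoch, J, J_tilde, grad_norm), and the
#'   `best_epoch` / `best_J_tilde` bookkeeping.
#' @export
fit_mfdl <- function(model, modalities, y, covariates = NULL, lambda = 0,
                     schedule = fit_schedule(), rho = 0.95, eps = 1e-6,
                     normalize_inputs = FALSE, standardize_response = FALSE) {
  stopifnot(inherits(model, "mfdl_model"), inherits(schedule, "fit_schedule"))
  inputs <- prepare_inputs(model, modalities, use_norm = FALSE)
  model$norm <- NULL
  if (normalize_inputs) {
    model$norm$inputs <- lapply(inputs, compute_norm)
    inputs <- Map(apply_norm, inputs, model$norm$inputs)
  }
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  y <- as.matrix(y)
  lambda_eff <- lambda
  if (standardize_response) {
    model$norm$y <- compute_norm(y)
    y <- apply_norm(y, model$norm$y)
    # keep the penalty on the footing of the original-scale objective:
    # J is divided by the (mean) response variance, so lambda is too
    lambda_eff <- lambda / mean(model$norm$y$scale^2)
  }
  if (nrow(y) != nrow(inputs[[1L]]))
    stop("'y' and the modalities disagree on sample count")
  params <- collect_params(model)
  state <- adadelta_init(params, rho = rho, eps = eps)
  n_max <- schedule$max_epochs
  hist_J <- numeric(n_max); hist_Jt <- numeric(n_max); hist_g <- numeric(n_max)
  n_done <- 0L
  best_Jt <- Inf; best_params <- params; best_epoch <- 0L
  for (epoch in seq_len(n_max)) {
    gc_out <- grad_core(model, inputs, covariates, y, lambda_eff)
    if (!is.finite(gc_out$J_tilde))
      stop("training diverged: non-finite loss at epoch ", epoch)
    hist_J[epoch] <- gc_out$J
    hist_Jt[epoch] <- gc_out$J_tilde
    hist_g[epoch] <- sqrt(sum(vapply(gc_out$grads, function(g) sum(g^2),
                                     numeric(1))))
    n_done <- epoch
    if (gc_out$J_tilde < best_Jt) {
      best_Jt <- gc_out$J_tilde; best_params <- params; best_epoch <- epoch
    }
    st <- adadelta_step(state, params, gc_out$grads)
    params <- st$params; state <- st$state
    model <- assign_params(model, params)
    if (epoch > schedule$patience) {
      ref <- hist_Jt[epoch - schedule$patience]
      if (abs(hist_Jt[epoch] - ref) / max(abs(ref), 1e-12) < schedule$tol)
        break
    }
  }
  # ADADELTA is not strictly monotone; keep the best iterate along the path
  model <- assign_params(model, best_params)
  history <- data.frame(epoch = seq_len(n_done), J = hist_J[seq_len(n_done)],
                        J_tilde = hist_Jt[seq_len(n_done)],
                        grad_norm = hist_g[seq_len(n_done)])
  attr(history, "best_epoch") <- best_epoch
  list(model = model, history = history, best_epoch = best_epoch,
       best_J_tilde = best_Jt)
}

#' Export a training history to CSV
#'
#' @param history the `history` data frame returned by [fit_mfdl()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Row-subset a modality object
#'
#' Subsets the samples of a [variant_function()] (keeping its marker
#' positions) or of a plain modality matrix; used for train/test splits.
#'
#' @param m a `variant_function` or numeric matrix.
#' @param idx row (sample) index vector.
#' @return An object of the same modality type with the selected samples.
#' @export
subset_modality <- function(m, idx) {
  if (inherits(m, "variant_function"))
    new_variant_function(m$values[idx, , drop = FALSE], m$positions01,
                         m$modality_id, positions_bp = m$positions_bp)
  else as.matrix(m)[idx, , drop = FALSE]
}

subset_modalities <- function(modalities, idx) {
  if (inherits(modalities, "variant_function") || is.matrix(modalities))
    modalities <- list(modalities)
  lapply(modalities, subset_modality, idx = idx)
}

#' Select the penalty parameter on a validation split or by k-fold CV
#'
#' For every candidate \eqn{\lambda}, fits on the training portion and
#' records the validation MSE; returns the candidate with minimal validation
#' MSE, breaking exact ties toward the larger (more regularized) value.
#'
#' @param fit_fun function `(modalities, y, covariates, lambda)` returning a
#'   fitted object with a `predict(object, modalities, covariates)` method.
#' @param modalities list of modality objects.
#' @param y phenotype matrix or vector.
#' @param covariates optional covariate matrix.
#' @param grid nonempty numeric vector of candidate penalties.
#' @param seed seed controlling the split/fold assignment.
#' @param val_frac validation fraction for the single-split mode.
#' @param folds if not `NULL`, use this many CV folds instead of one split.
#' @return List with `lambda` (the selection) and `table` (candidate
#'   validation MSEs).
#' @export
select_lambda <- function(fit_fun, modalities, y, covariates = NULL,
                          grid = c(0.1, 0.3, 1, 3, 10), seed = 1L,
                          val_frac = 0.25, folds = NULL) {
  if (length(grid) < 1L) stop("'lambda' grid must be nonempty")
  if (inherits(modalities, "variant_function") || is.matrix(modalities))
    modalities <- list(modalities)
  y <- as.matrix(y)
  n <- nrow(y)
  assign_fold <- with_seed(seed, {
    if (is.null(folds)) {
      f <- rep(1L, n)
      f[sample.int(n, max(1L, round(n * val_frac)))] <- 2L
      f
    } else {
      sample(rep_len(seq_len(folds), n))
    }
  })
  n_folds <- if (is.null(folds)) 1L else folds
  val_mse <- numeric(length(grid))
  for (li in seq_along(grid)) {
    errs <- numeric(n_folds)
    for (fd in seq_len(n_folds)) {
      val_idx <- if (is.null(folds)) which(assign_fold == 2L) else
        which(assign_fold == fd)
      tr_idx <- setdiff(seq_len(n), val_idx)
      fit <- fit_fun(subset_modalities(modalities, tr_idx),
                     y[tr_idx, , drop = FALSE],
                     if (is.null(covariates)) NULL else
                       covariates[tr_idx, , drop = FALSE],
                     grid[li])
      pred <- stats::predict(fit, subset_modalities(modalities, val_idx),
                             if (is.null(covariates)) NULL else
                               covariates[val_idx, , drop = FALSE])
      errs[fd] <- mse(y[val_idx, , drop = FALSE], pred)
    }
    val_mse[li] <- mean(errs)
  }
  best <- max(grid[val_mse == min(val_mse)])
  list(lambda = best, table = data.frame(lambda = grid, val_mse = val_mse))
}
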