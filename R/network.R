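# Internal layer engine: forward and reverse-mode passes over the discretized
# network. Every layer is a plain list tagged by 'kind'; basis evaluations
# (E, U) are fixed matrices computed at build time, so backpropagation is
# ordinary dense matrix algebra through the quadrature-discretized objective.
#
# Layer kinds:
#   ffirst  - variant-function layer: input is the Dirac design matrix Phi,
#             pre = Phi W E' (+ X alpha), no functional bias.
#   fhidden - function-to-function layer: pre = (Z U) W E' + 1 (E b)'.
#   fout    - function-to-vector layer:   pre = (Z U) W + 1 b'.
#   dense   - ordinary dense layer:       pre = Z W + 1 b'.
#
# U = E_in * grid weights encodes the trapezoid rule for the s-integral;
# E = out-basis evaluations at the grid points.

layer_forward <- function(layer, A, X = NULL, keep = FALSE) {
  act <- activation_fun(layer$act)
  cache <- NULL
  if (layer$kind == "ffirst") {
    pre <- A %*% layer$W %*% t(layer$E)
    if (!is.null(layer$alpha)) {
      if (is.null(X)) stop("layer expects covariates but none were supplied")
      pre <- pre + drop(X %*% layer$alpha)
    }
    Z <- act$f(pre)
    if (keep) cache <- list(A = A, pre = pre, Z = Z, X = X)
  } else if (layer$kind == "fhidden") {
    Ain <- A %*% layer$U
    pre <- Ain %*% layer$W %*% t(layer$E)
    pre <- pre + rep(drop(layer$E %*% layer$b), each = nrow(pre))
    Z <- act$f(pre)
    if (keep) cache <- list(A = Ain, pre = pre, Z = Z)
  } else if (layer$kind == "fout") {
    Ain <- A %*% layer$U
    pre <- Ain %*% layer$W
    pre <- pre + rep(layer$b, each = nrow(pre))
    Z <- act$f(pre)
    if (keep) cache <- list(A = Ain, pre = pre, Z = Z)
  } else if (layer$kind == "dense") {
    pre <- A %*% layer$W
    pre <- pre + rep(layer$b, each = nrow(pre))
    Z <- act$f(pre)
    if (keep) cache <- list(A = A, pre = pre, Z = Z)
  } else {
    stop("unknown layer kind '", layer$kind, "'")
  }
  if (any(!is.finite(Z)))
    stop("non-finite values in forward pass at layer kind '", layer$kind, "'")
  list(Z = Z, cache = cache)
}

# dZ: gradient of the loss wrt this layer's output. Returns gradients for the
# layer's own parameters plus dA, the gradient wrt the layer input.
layer_backward <- function(layer, cache, dZ) {
  act <- activation_fun(layer$act)
  dpre <- dZ * act$grad(cache$pre, cache$Z)
  if (layer$kind == "ffirst") {
    B <- dpre %*% layer$E
    g <- list(W = crossprod(cache$A, B))
    if (!is.null(layer$alpha))
      g$alpha <- drop(crossprod(cache$X, rowSums(dpre)))
    dA <- B %*% t(layer$W) # wrt Phi; unused upstream but cheap
    list(grads = g, dA = dA)
  } else if (layer$kind == "fhidden") {
    B <- dpre %*% layer$E
    list(grads = list(W = crossprod(cache$A, B), b = colSums(B)),
         dA = B %*% t(layer$W) %*% t(layer$U))
  } else if (layer$kind == "fout") {
    list(grads = list(W = crossprod(cache$A, dpre), b = colSums(dpre)),
         dA = dpre %*% t(layer$W) %*% t(layer$U))
  } else { # dense
    list(grads = list(W = crossprod(cache$A, dpre), b = colSums(dpre)),
         dA = dpre %*% t(layer$W))
  }
}

layers_forward <- function(layers, A, X = NULL, keep = FALSE) {
  caches <- if (keep) vector("list", length(layers)) else NULL
  for (d in seq_along(layers)) {
    out <- layer_forward(layers[[d]], A, X = X, keep = keep)
    A <- out$Z
    if (keep) caches[[d]] <- out$cache
  }
  list(Z = A, caches = caches)
}

layers_backward <- function(layers, caches, dZ) {
  grads <- vector("list", length(layers))
  for (d in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[d]], caches[[d]], dZ)
    grads[[d]] <- bk$grads
    dZ <- bk$dA
  }
  list(grads = grads, dA = dZ)
}

# --- parameter bookkeeping -------------------------------------------------

# Flat named list of every trainable array. Weight arrays carry names ending
# in ".W"; only those enter the L2 penalty (biases and covariate coefficients
# are excluded).
collect_params <- function(model) {
  out <- list()
  for (k in seq_along(model$subnets)) {
    layers <- model$subnets[[k]]$layers
    for (d in seq_along(layers)) {
      for (nm in intersect(c("W", "b", "alpha"), names(layers[[d]]))) {
        v <- layers[[d]][[nm]]
        if (!is.null(v)) out[[sprintf("s%d.l%d.%s", k, d, nm)]] <- v
      }
    }
  }
  for (d in seq_along(model$head$layers)) {
    for (nm in c("W", "b")) {
      v <- model$head$layers[[d]][[nm]]
      if (!is.null(v)) out[[sprintf("head.l%d.%s", d, nm)]] <- v
    }
  }
  out
}

assign_params <- function(model, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1L]]
    leaf <- parts[length(parts)]
    d <- as.integer(sub("^l", "", parts[length(parts) - 1L]))
    if (parts[1L] == "head") {
      model$head$layers[[d]][[leaf]] <- flat[[nm]]
    } else {
      k <- as.integer(sub("^s", "", parts[1L]))
      model$subnets[[k]]$layers[[d]][[leaf]] <- flat[[nm]]
    }
  }
  model
}

is_penalized <- function(param_names) endsWith(param_names, ".W")

penalty_sq_norm <- function(flat) {
  pen <- flat[is_penalized(names(flat))]
  sum(vapply(pen, function(w) sum(w^2), numeric(1)))
}

# --- seeded RNG ------------------------------------------------------------

# Evaluates 'expr' under set.seed(seed) and restores the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}
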