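#' Configuration of one modality subnet
#'
#' A functional subnet represents the modality as an omics variant function
#' and stacks a first functional layer, `n_hidden` function-to-function
#' hidden layers, and a function-to-vector output layer producing the
#' modality embedding. A dense subnet ("degenerate" path, for scalar or
#' low-dimensional modalities unsuited to functional smoothing) replaces the
#' functional machinery with ordinary matrices and vectors. An identity
#' subnet passes its input straight through, which together with the head
#' yields a plain feedforward network.
#'
#' @param kind "functional", "dense" or "identity".
#' @param p input dimension; required for dense and identity subnets.
#' @param n_hidden number of hidden functional layers (functional subnets).
#' @param order,n_basis B-spline order and number of basis functions used by
#'   every functional layer of this subnet.
#' @param grid_size quadrature grid size for the function-valued layers.
#' @param embedding_width width q of the modality embedding.
#' @param dense_widths hidden widths of a dense subnet (may be empty, giving
#'   a single linear map to the embedding).
#' @param activation activation for the hidden layers.
#' @param n_covariates number of scalar covariates fed into the first
#'   functional layer (0 for none).
#' @return An object of class `subnet_config`.
#' @export
subnet_config <- function(kind = c("functional", "dense", "identity"),
                          p = NULL, n_hidden = 1L, order = 5L, n_basis = 7L,
                          grid_size = 50L, embedding_width = 8L,
                          dense_widths = integer(0), activation = "tanh",
                          n_covariates = 0L) {
  kind <- match.arg(kind)
  if (kind %in% c("dense", "identity") && is.null(p))
    stop("'p' (input dimension) is required for ", kind, " subnets")
  embedding_width <- as.integer(embedding_width)
  if (kind == "identity") embedding_width <- as.integer(p)
  if (embedding_width < 1L) stop("'embedding_width' must be >= 1")
  structure(list(kind = kind, p = if (is.null(p)) NULL else as.integer(p),
                 n_hidden = as.integer(n_hidden), order = as.integer(order),
                 n_basis = as.integer(n_basis),
                 grid_size = as.integer(grid_size),
                 embedding_width = embedding_width,
                 dense_widths = as.integer(dense_widths),
                 activation = activation,
                 n_covariates = as.integer(n_covariates)),
            class = "subnet_config")
}

#' Configuration of the dense head on the shared representation
#'
#' @param hidden_widths integer vector of dense hidden-layer widths (may be
#'   empty for a purely linear head).
#' @param output_dim phenotype dimension (1 for a scalar phenotype).
#' @param activation activation for the hidden layers; the output layer uses
#'   the identity link.
#' @return An object of class `head_config`.
#' @export
head_config <- function(hidden_widths = 16L, output_dim = 1L,
                        activation = "tanh") {
  output_dim <- as.integer(output_dim)
  if (output_dim < 1L) stop("'output_dim' must be >= 1")
  structure(list(hidden_widths = as.integer(hidden_widths),
                 output_dim = output_dim, activation = activation),
            class = "head_config")
}

build_subnet <- function(config) {
  layers <- list()
  if (config$kind == "functional") {
    grid <- quad_grid(config$grid_size)
    basis <- bspline_system(config$order, config$n_basis)
    E <- eval_basis(basis, grid$points)
    U <- E * grid$weights
    J <- config$n_basis
    l1 <- list(kind = "ffirst", W = glorot(J, J), E = E,
               act = config$activation)
    if (config$n_covariates > 0L) l1$alpha <- rep(0, config$n_covariates)
    layers[[1L]] <- l1
    # The s-integral against a B-spline basis function averages the hidden
    # function with weight ~ 1/J, so layers downstream of the quadrature
    # operator see inputs attenuated by that factor. Scaling their initial
    # weights by J_in restores unit-scale pre-activations (Glorot assumes
    # unit-scale inputs); without it, deep functional stacks start with
    # vanishing gradients.
    for (d in seq_len(config$n_hidden)) {
      layers[[length(layers) + 1L]] <-
        list(kind = "fhidden", W = glorot(J, J) * J, b = rep(0, J), U = U,
             E = E, act = config$activation)
    }
    layers[[length(layers) + 1L]] <-
      list(kind = "fout", W = glorot(J, config$embedding_width) * J,
           b = rep(0, config$embedding_width), U = U, act = "identity")
    list(config = config, in_basis = basis, grid = grid, layers = layers)
  } else if (config$kind == "dense") {
    widths <- c(config$p, config$dense_widths, config$embedding_width)
    acts <- c(rep(config$activation, length(config$dense_widths)), "identity")
    for (d in seq_len(length(widths) - 1L)) {
      layers[[d]] <- list(kind = "dense",
                          W = glorot(widths[d], widths[d + 1L]),
                          b = rep(0, widths[d + 1L]), act = acts[d])
    }
    list(config = config, layers = layers)
  } else { # identity
    list(config = config, layers = list())
  }
}

#' Build a multimodal functional deep learning model
#'
#' Assembles one subnet per modality and a dense head over the concatenated
#' modality embeddings (the shared representation). All weight matrices are
#' initialized Glorot-uniform from `seed`; biases and covariate coefficients
#' start at zero. The same seed always yields bitwise-identical parameters.
#'
#' @param subnet_configs list of [subnet_config()] objects, one per modality,
#'   in modality order.
#' @param head_cfg a [head_config()], or `NULL` for models whose single
#'   subnet output is already the prediction (used by the single-network
#'   functional baseline).
#' @param seed integer seed for parameter initialization.
#' @return An object of class `mfdl_model`.
#' @export
build_mfdl <- function(subnet_configs, head_cfg = head_config(), seed = 1L) {
  if (inherits(subnet_configs, "subnet_config"))
    subnet_configs <- list(subnet_configs)
  if (length(subnet_configs) < 1L) stop("at least one modality is required")
  for (sc in subnet_configs) stopifnot(inherits(sc, "subnet_config"))
  model <- with_seed(seed, {
    subnets <- lapply(subnet_configs, build_subnet)
    shared_width <- sum(vapply(subnets, function(s)
      s$config$embedding_width, integer(1)))
    head <- NULL
    if (!is.null(head_cfg)) {
      stopifnot(inherits(head_cfg, "head_config"))
      widths <- c(shared_width, head_cfg$hidden_widths, head_cfg$output_dim)
      acts <- c(rep(head_cfg$activation, length(head_cfg$hidden_widths)),
                "identity")
      hl <- vector("list", length(widths) - 1L)
      for (d in seq_along(hl)) {
        hl[[d]] <- list(kind = "dense", W = glorot(widths[d], widths[d + 1L]),
                        b = rep(0, widths[d + 1L]), act = acts[d])
      }
      head <- list(config = head_cfg, layers = hl)
    }
    list(subnets = subnets, head = head, shared_width = shared_width,
         seed = as.integer(seed))
  })
  class(model) <- "mfdl_model"
  model
}

#' @export
print.mfdl_model <- function(x, ...) {
  kinds <- vapply(x$subnets, function(s) s$config$kind, character(1))
  qs <- vapply(x$subnets, function(s) s$config$embedding_width, integer(1))
  cat(sprintf("Multimodal functional DL model: %d modalit%s (%s), shared width %d\n",
              length(x$subnets), if (length(x$subnets) == 1L) "y" else "ies",
              paste(sprintf("%s q=%d", kinds, qs), collapse = ", "),
              x$shared_width))
  np <- sum(vapply(collect_params(x), length, integer(1)))
  cat(sprintf("  head: %s -> %s; %d trainable parameters\n",
              if (is.null(x$head)) "none (subnet output is the prediction)"
              else paste(x$head$config$hidden_widths, collapse = "-"),
              if (is.null(x$head)) "" else x$head$config$output_dim, np))
  invisible(x)
}

# Column-wise location/scale normalization of subnet input matrices and of
# the response, fixed from the training batch when a model is fitted with
# normalization enabled and stored on the model so predictions stay
# consistent.
compute_norm <- function(X) {
  list(center = colMeans(X),
       scale = pmax(apply(X, 2L, stats::sd), 1e-8))
}

apply_norm <- function(X, nm) {
  sweep(sweep(X, 2L, nm$center, `-`), 2L, nm$scale, `/`)
}

unapply_norm <- function(X, nm) {
  sweep(sweep(X, 2L, nm$scale, `*`), 2L, nm$center, `+`)
}

# Turn user-facing modality objects into the per-subnet input matrices:
# the Dirac design matrix for functional subnets, the raw matrix otherwise.
prepare_inputs <- function(model, modalities, use_norm = TRUE) {
  if (inherits(modalities, "variant_function") || is.matrix(modalities))
    modalities <- list(modalities)
  if (length(modalities) != length(model$subnets))
    stop("model has ", length(model$subnets), " subnets but ",
         length(modalities), " modalities were supplied")
  inputs <- vector("list", length(modalities))
  for (k in seq_along(modalities)) {
    cfg <- model$subnets[[k]]$config
    m <- modalities[[k]]
    if (cfg$kind == "functional") {
      if (!inherits(m, "variant_function"))
        stop("modality ", k, " must be a variant_function for a functional subnet")
      inputs[[k]] <- dirac_design(m, model$subnets[[k]]$in_basis)
    } else {
      m <- as.matrix(m)
      if (ncol(m) != cfg$p)
        stop("modality ", k, " has ", ncol(m), " columns; subnet expects ",
             cfg$p)
      inputs[[k]] <- m
    }
  }
  ns <- vapply(inputs, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("modalities disagree on sample count: ", paste(ns, collapse = ", "))
  if (use_norm && !is.null(model$norm$inputs))
    inputs <- Map(apply_norm, inputs, model$norm$inputs)
  inputs
}

# Core forward pass on prepared inputs; keep = TRUE retains caches for
# backpropagation.
forward_core <- function(model, inputs, X = NULL, keep = FALSE) {
  emb <- vector("list", length(model$subnets))
  sub_caches <- if (keep) vector("list", length(model$subnets)) else NULL
  for (k in seq_along(model$subnets)) {
    sn <- model$subnets[[k]]
    if (sn$config$kind == "identity") {
      emb[[k]] <- inputs[[k]]
      if (keep) sub_caches[[k]] <- list()
    } else {
      out <- layers_forward(sn$layers, inputs[[k]], X = X, keep = keep)
      emb[[k]] <- out$Z
      if (keep) sub_caches[[k]] <- out$caches
    }
  }
  Zwide <- concat_shared(emb)
  if (is.null(model$head)) {
    list(y_hat = Zwide, emb = emb, sub_caches = sub_caches,
         head_caches = NULL, Zwide = Zwide)
  } else {
    out <- layers_forward(model$head$layers, Zwide, keep = keep)
    list(y_hat = out$Z, emb = emb, sub_caches = sub_caches,
         head_caches = out$caches, Zwide = Zwide)
  }
}

#' Forward pass of a multimodal model
#'
#' Runs every modality through its subnet, concatenates the embeddings into
#' the shared representation and applies the dense head.
#'
#' @param model an [build_mfdl()] model.
#' @param modalities list of modality inputs in modality order:
#'   [variant_function()] objects for functional subnets, numeric matrices
#'   for dense or identity subnets.
#' @param covariates optional `n x q` covariate matrix routed to functional
#'   subnets built with `n_covariates = q`.
#' @return `n x output_dim` matrix of predictions.
#' @export
mfdl_forward <- function(model, modalities, covariates = NULL) {
  stopifnot(inherits(model, "mfdl_model"))
  inputs <- prepare_inputs(model, modalities)
  if (!is.null(covariates)) covariates <- as.matrix(covariates)
  y_hat <- forward_core(model, inputs, X = covariates)$y_hat
  if (!is.null(model$norm$y)) y_hat <- unapply_norm(y_hat, model$norm$y)
  y_hat
}

#' @rdname mfdl_forward
#' @param object an `mfdl_model`.
#' @param ... unused.
#' @export
predict.mfdl_model <- function(object, modalities, covariates = NULL, ...) {
  mfdl_forward(object, modalities, covariates)
}

#' Concatenate modality embeddings into the shared representation
#'
#' @param embeddings list of `n x q_k` matrices in modality order.
#' @return `n x sum(q_k)` matrix; columns keep modality order.
#' @export
concat_shared <- function(embeddings) {
  stopifnot(is.list(embeddings), length(embeddings) >= 1L)
  ns <- vapply(embeddings, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("embeddings disagree on sample count: ", paste(ns, collapse = ", "))
  do.call(cbind, embeddings)
}

#' Number of activation-bearing hidden layers of a model
#'
#' Counts the layers to which the nonlinear activation is applied: the first
#' and hidden functional layers of each subnet, dense subnet hidden layers,
#' and the head's hidden layers. Linear output/embedding layers do not count.
#'
#' @param model an `mfdl_model`.
#' @return integer count.
#' @export
n_hidden_layers <- function(model) {
  n <- 0L
  for (sn in model$subnets)
    n <- n + sum(vapply(sn$layers, function(l) l$act != "identity", logical(1)))
  if (!is.null(model$head))
    n <- n + sum(vapply(model$head$layers, function(l) l$act != "identity",
                        logical(1)))
  n
}
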