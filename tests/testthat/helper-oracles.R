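# Independent oracles used across the suite. Each reimplements the quantity
# under test by the most direct route available (recursions, explicit loops,
# augmented least squares), deliberately avoiding the package's own code
# paths.

# Cox-de Boor recursion, one basis function at one point (interior points).
cox_de_boor <- function(knots, j, k, x) {
  if (k == 1L)
    return(as.numeric(knots[j] <= x && x < knots[j + 1L]))
  d1 <- knots[j + k - 1L] - knots[j]
  d2 <- knots[j + k] - knots[j + 1L]
  t1 <- if (d1 > 0) (x - knots[j]) / d1 * cox_de_boor(knots, j, k - 1L, x) else 0
  t2 <- if (d2 > 0) (knots[j + k] - x) / d2 * cox_de_boor(knots, j + 1L, k - 1L, x) else 0
  t1 + t2
}

oracle_bspline_row <- function(sys, x) {
  vapply(seq_len(sys$n_basis), function(j) cox_de_boor(sys$knots, j, sys$order, x),
         numeric(1))
}

# Explicit double-loop Dirac design: sum_j g[i, j] * eta_l(t_j).
oracle_dirac_design <- function(values, pos01, basis) {
  n <- nrow(values); p <- ncol(values); J <- basis$n_basis
  eta <- eval_basis(basis, pos01) # p x J of basis values at marker positions
  out <- matrix(0, n, J)
  for (i in seq_len(n))
    for (l in seq_len(J))
      for (j in seq_len(p))
        out[i, l] <- out[i, l] + values[i, j] * eta[j, l]
  out
}

# Trace-formula RV with explicit loops over matrix products.
oracle_rv <- function(Y, Yh) {
  Y <- scale(as.matrix(Y), center = TRUE, scale = FALSE)
  Yh <- scale(as.matrix(Yh), center = TRUE, scale = FALSE)
  n <- nrow(Y)
  S1 <- Y %*% t(Y); S2 <- Yh %*% t(Yh)
  tr <- function(M) sum(diag(M))
  tr(S1 %*% S2) / sqrt(tr(S1 %*% S1) * tr(S2 %*% S2))
}

# Ridge by augmented least squares (QR), penalised columns flagged in 'pen';
# lambda on the same footing as the networks' objective.
oracle_ridge <- function(A, y, pen, lambda) {
  n <- nrow(A)
  aug <- diag(sqrt(n * lambda / 2) * as.numeric(pen))
  aug <- aug[rowSums(aug != 0) > 0, , drop = FALSE]
  qr.solve(rbind(A, aug), rbind(as.matrix(y), matrix(0, nrow(aug), ncol(as.matrix(y)))))
}

# Scalar ADADELTA recursion.
oracle_adadelta_scalar <- function(gs, rho = 0.95, eps = 1e-6) {
  Eg <- 0; Ed <- 0; x <- 0; deltas <- numeric(length(gs))
  for (i in seq_along(gs)) {
    g <- gs[i]
    Eg <- rho * Eg + (1 - rho) * g^2
    d <- -sqrt(Ed + eps) / sqrt(Eg + eps) * g
    Ed <- rho * Ed + (1 - rho) * d^2
    x <- x + d
    deltas[i] <- d
  }
  list(x = x, deltas = deltas)
}

# Central finite differences of the regularized loss for randomly chosen
# coordinates of every parameter array.
fd_check <- function(model, modalities, y, covariates = NULL, lambda = 0,
                     n_per_param = 2L, h = 1e-5) {
  flat <- mfdl:::collect_params(model)
  grads <- mfdl_gradients(model, modalities, y, covariates, lambda)
  obj <- function(fl) {
    m2 <- mfdl:::assign_params(model, fl)
    yh <- mfdl_forward(m2, modalities, covariates)
    mfdl_loss(y, yh, m2, lambda)$J_tilde
  }
  worst <- 0
  for (nm in names(flat)) {
    for (r in seq_len(n_per_param)) {
      i <- sample.int(length(flat[[nm]]), 1L)
      fp <- flat; fp[[nm]][i] <- fp[[nm]][i] + h
      fm <- flat; fm[[nm]][i] <- fm[[nm]][i] - h
      fd <- (obj(fp) - obj(fm)) / (2 * h)
      an <- grads[[nm]][i]
      worst <- max(worst, abs(fd - an) / max(abs(fd), abs(an), 1e-8))
    }
  }
  worst
}

# Independent plain feedforward network: explicit per-sample loops.
oracle_nn_forward <- function(X, Ws, bs, act = tanh) {
  n <- nrow(X)
  out <- matrix(NA_real_, n, length(bs[[length(bs)]]))
  for (i in seq_len(n)) {
    z <- X[i, ]
    for (d in seq_along(Ws)) {
      z <- drop(z %*% Ws[[d]]) + bs[[d]]
      if (d < length(Ws)) z <- act(z)
    }
    out[i, ] <- z
  }
  out
}

# Brute-force linear effect: triple loop over (sample, marker, basis fn).
oracle_linear_effect <- function(vf, a, C, basis) {
  g <- vf$values; t <- vf$positions01
  n <- nrow(g); p <- ncol(g); J <- basis$n_basis; d <- ncol(as.matrix(C))
  C <- as.matrix(C)
  eta <- eval_basis(basis, t)
  out <- matrix(0, n, d)
  for (i in seq_len(n))
    for (u in seq_len(d))
      for (l in seq_len(J))
        for (j in seq_len(p))
          out[i, u] <- out[i, u] + a * g[i, j] * eta[j, l] * C[l, u]
  out
}

# Brute-force nonlinear effect: quadruple loop over (l, marker, s, column).
oracle_nonlinear_effect <- function(vf, d1, d2, C, s_points,
                                    a_l = c(2 / 3, -2, 2),
                                    c_l = c(2 / 3, -2, 2),
                                    e = c(1 / 3, 3 / 2, 3)) {
  g <- vf$values; t <- vf$positions01
  n <- nrow(g); C <- as.matrix(C); nd <- ncol(C)
  V <- matrix(0, n, length(s_points))
  for (i in seq_len(n))
    for (si in seq_along(s_points))
      for (l in seq_along(a_l)) {
        acc <- 0
        for (j in seq_len(ncol(g)))
          acc <- acc + g[i, j]^e[l] * cos(a_l[l] * t[j] + d1[l])
        V[i, si] <- V[i, si] + c_l[l] * acc * sin(a_l[l] * s_points[si] + d2[l])
      }
  out <- matrix(0, n, nd)
  for (i in seq_len(n))
    for (u in seq_len(nd))
      out[i, u] <- sum(V[i, ] * C[, u])
  out
}

# Random small genotype-like variant function.
rand_vf <- function(n, p, seed = NULL) {
  draw <- function() {
    vals <- matrix(sample(0:2, n * p, replace = TRUE), n, p)
    pos <- sort(sample.int(10000L, p))
    variant_function(vals, pos)
  }
  if (is.null(seed)) draw() else mfdl:::with_seed(seed, draw())
}

# Deterministic constant-MAF law for well-behaved small fixtures.
const_maf <- function(maf) function(p) rep(maf, p)

# Variant function straight from unit-interval positions.
new_vf_for_test <- function(values, pos01) {
  mfdl:::new_variant_function(as.matrix(values), pos01)
}
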