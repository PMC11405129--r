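test_that("the regularized loss follows its printed form", {
  y <- matrix(c(0, 2), 2, 1)
  expect_equal(mfdl_loss(y, y)$J, 0)
  expect_equal(mfdl_loss(y, y, lambda = 0)$J_tilde, 0)
  expect_equal(mfdl_loss(y, matrix(0, 2, 1))$J, 2) # (0 + 4) / 2

  # J_tilde = J + lambda/2 * ||W||^2 with biases excluded
  model <- build_mfdl(list(subnet_config("dense", p = 2,
                                         embedding_width = 2)),
                      head_config(integer(0), 1), seed = 1)
  flat <- mfdl:::collect_params(model)
  flat[["s1.l1.W"]] <- matrix(c(1, 1, 1, 1), 2, 2)
  flat[["head.l1.W"]] <- matrix(0, 2, 1)
  flat[["s1.l1.b"]] <- c(50, 50) # biases must not enter the penalty
  model <- mfdl:::assign_params(model, flat)
  out <- mfdl_loss(y, matrix(0, 2, 1), model, lambda = 1)
  expect_equal(out$J_tilde, 2 + 1 / 2 * 4)
  expect_error(mfdl_loss(y, matrix(0, 3, 1)), "identical dimensions")
})

test_that("analytic gradients match central finite differences everywhere", {
  # all layer types: functional first/hidden/output with covariates, dense
  # subnet, identity subnet, dense head; three seeds
  for (seed in c(1L, 2L, 3L)) {
    set.seed(seed)
    vf <- rand_vf(6, 8)
    X <- matrix(rnorm(12), 6, 2)
    covs <- matrix(rnorm(6), 6, 1)
    y <- matrix(rnorm(12), 6, 2)
    model <- build_mfdl(
      list(subnet_config("functional", n_hidden = 1, order = 3, n_basis = 5,
                         grid_size = 20, embedding_width = 3,
                         n_covariates = 1),
           subnet_config("dense", p = 2, dense_widths = 4L,
                         embedding_width = 3)),
      head_config(6, 2), seed = seed)
    worst <- fd_check(model, list(vf, X), y, covariates = covs,
                      lambda = 0.3, n_per_param = 2L)
    expect_lt(worst, 1e-4)
  }
  # single functional network with no head (direct functional output)
  model <- build_mfdl(list(subnet_config("functional", n_hidden = 2,
                                         embedding_width = 1)),
                      head_cfg = NULL, seed = 4)
  vf <- rand_vf(5, 10, seed = 4)
  y <- mfdl:::with_seed(5, matrix(rnorm(5), 5, 1))
  expect_lt(fd_check(model, list(vf), y, lambda = 0.1), 1e-4)
})

test_that("penalty gradient is exactly lambda * W at zero residual", {
  model <- build_mfdl(list(subnet_config("dense", p = 2,
                                         embedding_width = 2)),
                      head_config(integer(0), 1), seed = 6)
  X <- matrix(rnorm(8), 4, 2)
  y <- mfdl_forward(model, list(X)) # zero residual by construction
  g0 <- mfdl_gradients(model, list(X), y, lambda = 0)
  expect_true(all(vapply(g0, function(g) max(abs(g)) < 1e-12, logical(1))))
  lam <- 0.7
  g <- mfdl_gradients(model, list(X), y, lambda = lam)
  flat <- mfdl:::collect_params(model)
  for (nm in names(flat)) {
    if (endsWith(nm, ".W"))
      expect_equal(g[[nm]], lam * flat[[nm]], tolerance = 1e-10)
    else
      expect_lt(max(abs(g[[nm]])), 1e-12)
  }
})

test_that("ADADELTA updates follow the accumulator recursions", {
  params <- list(w = 0)
  st <- adadelta_init(params, rho = 0.95, eps = 1e-6)
  # zero gradient: nothing moves, accumulators decay
  st$acc_grad_sq$w <- 0.4
  out <- adadelta_step(st, params, list(w = 0))
  expect_equal(out$params$w, 0)
  expect_equal(out$state$acc_grad_sq$w, 0.95 * 0.4)

  # first unit-gradient step from a fresh state
  st <- adadelta_init(params)
  out <- adadelta_step(st, params, list(w = 1))
  d1 <- -sqrt(1e-6) / sqrt(0.05 * 1 + 1e-6)
  expect_equal(out$params$w, d1, tolerance = 1e-12)
  expect_equal(d1, -4.4719e-3, tolerance = 1e-4)

  # a long constant-gradient run matches the scalar oracle step for step;
  # the step magnitude grows monotonically toward its fixed point 1 with a
  # decelerating growth rate (the recursions approach steady state slowly,
  # so strict stabilization is asymptotic, not reached at 1e4 steps)
  oracle <- oracle_adadelta_scalar(rep(1, 1e4))
  p <- list(w = 0); st <- adadelta_init(p)
  deltas <- numeric(1e4)
  for (i in 1:1e4) {
    prev <- p$w
    out <- adadelta_step(st, p, list(w = 1))
    p <- out$params; st <- out$state
    deltas[i] <- p$w - prev
  }
  expect_identical(p$w, oracle$x)
  # deltas recovered as differences of the running sum: equal up to the
  # rounding of that subtraction
  expect_equal(deltas, oracle$deltas, tolerance = 1e-12)
  d_abs <- abs(deltas)
  expect_true(all(diff(d_abs) > 0))
  expect_true(all(d_abs < 1))
  growth <- function(win) (d_abs[win[2]] - d_abs[win[1]]) / d_abs[win[1]]
  expect_lt(growth(c(9900L, 10000L)), growth(c(100L, 200L)))
  expect_lt(growth(c(9900L, 10000L)), 0.01)
})

test_that("fitting is seeded, shrinks with lambda, and honors max_epochs", {
  vf <- rand_vf(30, 10, seed = 31)
  set.seed(32)
  y <- matrix(rowSums(vf$values) * 0.3 + rnorm(30, sd = 0.2), 30, 1)
  arch <- list(subnet_config("functional", n_hidden = 0, order = 3,
                             n_basis = 5, embedding_width = 4))
  model <- build_mfdl(arch, head_config(4, 1), seed = 33)

  # max_epochs = 0 returns the initial model untouched
  f0 <- fit_mfdl(model, list(vf), y, schedule = fit_schedule(0L))
  expect_identical(mfdl:::collect_params(f0$model),
                   mfdl:::collect_params(model))
  expect_equal(nrow(f0$history), 0L)

  # identical runs give identical histories
  f1 <- fit_mfdl(model, list(vf), y, lambda = 0.1,
                 schedule = fit_schedule(150))
  f2 <- fit_mfdl(model, list(vf), y, lambda = 0.1,
                 schedule = fit_schedule(150))
  expect_identical(f1$history, f2$history)

  # heavier penalty leaves strictly smaller weight norm from the same seed
  w_norm <- function(f) {
    flat <- mfdl:::collect_params(f$model)
    sqrt(sum(vapply(flat[endsWith(names(flat), ".W")],
                    function(w) sum(w^2), numeric(1))))
  }
  fa <- fit_mfdl(model, list(vf), y, lambda = 0,
                 schedule = fit_schedule(400))
  fb <- fit_mfdl(model, list(vf), y, lambda = 10,
                 schedule = fit_schedule(400))
  expect_lt(w_norm(fb), w_norm(fa))
})

test_that("training loss is non-increasing up to ADADELTA tolerance", {
  vf <- rand_vf(40, 12, seed = 41)
  set.seed(42)
  y <- matrix(0.2 * rowSums(vf$values) + rnorm(40, sd = 0.3), 40, 1)
  model <- build_mfdl(list(subnet_config("functional", n_hidden = 0,
                                         embedding_width = 4)),
                      head_config(8, 1), seed = 43)
  fit <- fit_mfdl(model, list(vf), y, lambda = 0.1,
                  schedule = fit_schedule(800, tol = 0),
                  normalize_inputs = TRUE, standardize_response = TRUE)
  Jt <- fit$history$J_tilde
  increases <- sum(diff(Jt) > 1e-8)
  expect_lt(increases / length(Jt), 0.05)
})

test_that("a noiseless in-span linear problem is fit to near zero", {
  g <- simulate_genotypes(genotype_model(50, 20, ld_rho = 0.5,
                                         maf_law = const_maf(0.3)),
                          seed = 21)
  bs <- bspline_system(2, 4)
  C <- mfdl:::with_seed(22, matrix(rnorm(4), 4, 1))
  y <- gen_linear_effect(g, a = 0.2, C = C, basis = bs)
  model <- build_mfdl(
    list(subnet_config("functional", n_hidden = 0, order = 2, n_basis = 4,
                       embedding_width = 4, activation = "identity")),
    head_config(integer(0), 1), seed = 5)
  fit <- fit_mfdl(model, list(g), y, lambda = 0,
                  schedule = fit_schedule(5000, tol = 1e-9, patience = 100))
  expect_lt(mfdl_loss(y, mfdl_forward(fit$model, list(g)))$J, 1e-3)
})

test_that("lambda selection returns the validation argmin from the grid", {
  g <- simulate_genotypes(genotype_model(60, 15, ld_rho = 0.5,
                                         maf_law = const_maf(0.25)),
                          seed = 51)
  C <- mfdl:::with_seed(52, matrix(rnorm(7), 7, 1))
  y <- gen_linear_effect(g, a = 0.4, C = C) +
    mfdl:::with_seed(53, matrix(rnorm(60, sd = 0.5), 60, 1))
  flm_fitter <- function(mods, yy, cov, lambda)
    fit_flm(mods, yy, cov, lambda = lambda)

  # singleton grid
  sel1 <- select_lambda(flm_fitter, list(g), y, grid = 1, seed = 2)
  expect_equal(sel1$lambda, 1)
  expect_error(select_lambda(flm_fitter, list(g), y, grid = numeric(0)),
               "nonempty")

  grid <- c(0.1, 0.3, 1, 3, 10)
  sel <- select_lambda(flm_fitter, list(g), y, grid = grid, seed = 2)
  expect_true(sel$lambda %in% grid)
  chosen_mse <- sel$table$val_mse[sel$table$lambda == sel$lambda]
  expect_true(all(chosen_mse <= sel$table$val_mse))

  # k-fold mode agrees on the contract too
  self <- select_lambda(flm_fitter, list(g), y, grid = grid, seed = 2,
                        folds = 3)
  expect_true(self$lambda %in% grid)
})
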