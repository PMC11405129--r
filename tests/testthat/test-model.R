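test_that("model assembly concatenates embeddings in modality order", {
  arch <- list(subnet_config("functional", embedding_width = 8),
               subnet_config("functional", embedding_width = 8))
  model <- build_mfdl(arch, head_config(16, 1), seed = 1)
  expect_equal(model$shared_width, 16L)
  expect_equal(nrow(model$head$layers[[1]]$W), 16L)

  e1 <- matrix(1, 5, 2); e2 <- matrix(2, 5, 3)
  Z <- concat_shared(list(e1, e2))
  expect_equal(dim(Z), c(5L, 5L))
  expect_equal(Z[, 1:2], e1)
  expect_identical(concat_shared(list(e1)), e1)
  expect_equal(ncol(concat_shared(list(e1, e2, matrix(0, 5, 4)))), 9L)
  expect_error(concat_shared(list(e1, matrix(0, 4, 2))), "sample count")
})

test_that("identical seeds give bitwise-identical parameters", {
  arch <- list(subnet_config("functional"), subnet_config("dense", p = 3))
  m1 <- build_mfdl(arch, head_config(16, 2), seed = 99)
  m2 <- build_mfdl(arch, head_config(16, 2), seed = 99)
  expect_identical(mfdl:::collect_params(m1), mfdl:::collect_params(m2))
  m3 <- build_mfdl(arch, head_config(16, 2), seed = 100)
  expect_false(identical(mfdl:::collect_params(m1),
                         mfdl:::collect_params(m3)))
})

test_that("scalar modalities take the degenerate dense path", {
  sn <- build_mfdl(list(subnet_config("dense", p = 1, embedding_width = 4)),
                   head_config(8, 1), seed = 2)$subnets[[1]]
  expect_null(sn$in_basis)
  expect_true(all(vapply(sn$layers, function(l) l$kind == "dense",
                         logical(1))))
})

test_that("zero-parameter model predicts its output bias", {
  arch <- list(subnet_config("functional"), subnet_config("dense", p = 2))
  model <- build_mfdl(arch, head_config(16, 2), seed = 5)
  flat <- mfdl:::collect_params(model)
  flat <- lapply(flat, function(x) x * 0)
  flat[["head.l2.b"]] <- c(1.25, -0.5)
  model <- mfdl:::assign_params(model, flat)
  vf <- rand_vf(6, 10, seed = 5)
  pred <- mfdl_forward(model, list(vf, matrix(rnorm(12), 6, 2)))
  expect_equal(pred, matrix(c(1.25, -0.5), 6, 2, byrow = TRUE))
})

test_that("the all-identity multimodal chain equals its matrix composition", {
  model <- build_mfdl(
    list(subnet_config("functional", n_hidden = 0, order = 3, n_basis = 5,
                       embedding_width = 5, activation = "identity")),
    head_config(integer(0), 1), seed = 7)
  vf <- rand_vf(5, 9, seed = 8)
  Phi <- dirac_design(vf, model$subnets[[1]]$in_basis)
  grid <- model$subnets[[1]]$grid
  E <- eval_basis(model$subnets[[1]]$in_basis, grid$points)
  S <- t(E) %*% (E * grid$weights)
  L <- model$subnets[[1]]$layers
  expected <- Phi %*% L[[1]]$W %*% S %*% L[[2]]$W %*%
    model$head$layers[[1]]$W +
    matrix(L[[2]]$b %*% model$head$layers[[1]]$W + model$head$layers[[1]]$b,
           5, 1)
  expect_equal(mfdl_forward(model, list(vf)), expected, tolerance = 1e-10)
})

test_that("predictions are row-wise: permuting samples permutes predictions", {
  arch <- list(subnet_config("functional"), subnet_config("dense", p = 2))
  model <- build_mfdl(arch, head_config(8, 1), seed = 11)
  vf <- rand_vf(7, 8, seed = 11)
  X <- matrix(rnorm(14), 7, 2)
  pred <- mfdl_forward(model, list(vf, X))
  perm <- c(3, 1, 2, 7, 6, 5, 4)
  pred_p <- mfdl_forward(model, list(
    new_vf_for_test(vf$values[perm, ], vf$positions01),
    X[perm, , drop = FALSE]))
  expect_equal(pred_p, pred[perm, , drop = FALSE], tolerance = 1e-12)
})

test_that("an all-dense model equals an independent plain network forward", {
  model <- build_mfdl(
    list(subnet_config("dense", p = 4, dense_widths = 6L,
                       embedding_width = 3)),
    head_config(5, 2), seed = 13)
  X <- mfdl:::with_seed(14, matrix(rnorm(24), 6, 4))
  L <- c(model$subnets[[1]]$layers, model$head$layers)
  Ws <- lapply(L, `[[`, "W"); bs <- lapply(L, `[[`, "b")
  # the embedding layer is linear; fold it by applying tanh only on
  # activation-bearing layers in the oracle
  oracle <- matrix(NA_real_, 6, 2)
  for (i in 1:6) {
    z <- X[i, ]
    for (d in seq_along(L)) {
      z <- drop(z %*% Ws[[d]]) + bs[[d]]
      if (L[[d]]$act == "tanh") z <- tanh(z)
    }
    oracle[i, ] <- z
  }
  expect_lt(max(abs(mfdl_forward(model, list(X)) - oracle)), 1e-10)
})

test_that("predictions are continuous in every parameter", {
  arch <- list(subnet_config("functional", embedding_width = 4))
  model <- build_mfdl(arch, head_config(6, 1), seed = 17)
  vf <- rand_vf(5, 6, seed = 17)
  base <- mfdl_forward(model, list(vf))
  flat <- mfdl:::collect_params(model)
  eps <- 1e-6
  set.seed(18)
  for (nm in names(flat)) {
    i <- sample.int(length(flat[[nm]]), 1)
    f2 <- flat; f2[[nm]][i] <- f2[[nm]][i] + eps
    pred <- mfdl_forward(mfdl:::assign_params(model, f2), list(vf))
    ratio <- max(abs(pred - base)) / eps
    expect_true(is.finite(ratio))
    expect_lt(ratio, 1e3)
  }
})

test_that("swapping modalities and the matching head columns is a no-op", {
  arch <- list(subnet_config("functional", embedding_width = 3),
               subnet_config("dense", p = 2, embedding_width = 4))
  model <- build_mfdl(arch, head_config(8, 1), seed = 19)
  vf <- rand_vf(5, 6, seed = 19)
  X <- matrix(rnorm(10), 5, 2)
  pred <- mfdl_forward(model, list(vf, X))
  # swapped model: subnets in reverse order, head input rows permuted
  swapped <- model
  swapped$subnets <- model$subnets[c(2, 1)]
  swapped$head$layers[[1]]$W <-
    model$head$layers[[1]]$W[c(4:7, 1:3), , drop = FALSE]
  expect_equal(mfdl_forward(swapped, list(X, vf)), pred, tolerance = 1e-12)
})

test_that("models round-trip through JSON bit-exactly", {
  arch <- list(subnet_config("functional", n_hidden = 1, embedding_width = 4),
               subnet_config("dense", p = 3, dense_widths = 5L))
  model <- build_mfdl(arch, head_config(c(8L, 4L), 2), seed = 23)
  vf <- rand_vf(6, 7, seed = 23)
  X <- matrix(rnorm(18), 6, 3)
  y <- matrix(rnorm(12), 6, 2)
  fit <- fit_mfdl(model, list(vf, X), y, lambda = 0.1,
                  schedule = fit_schedule(30), normalize_inputs = TRUE,
                  standardize_response = TRUE)
  path <- tempfile(fileext = ".json")
  write_mfdl(fit$model, path)
  model2 <- read_mfdl(path)
  expect_identical(mfdl:::collect_params(fit$model),
                   mfdl:::collect_params(model2))
  expect_identical(fit$model$norm, model2$norm)
  expect_identical(mfdl_forward(fit$model, list(vf, X)),
                   mfdl_forward(model2, list(vf, X)))
})

test_that("hidden-layer counting reflects activation-bearing layers", {
  m <- build_mfdl(list(subnet_config("functional", n_hidden = 2,
                                     embedding_width = 1)),
                  head_cfg = NULL, seed = 1)
  expect_equal(n_hidden_layers(m), 3L)
  m2 <- build_mfdl(list(subnet_config("dense", p = 3, dense_widths = 4L)),
                   head_config(16, 1), seed = 1)
  expect_equal(n_hidden_layers(m2), 2L)
})
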