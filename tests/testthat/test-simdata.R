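test_that("the rare-skewed MAF law hits its mass targets", {
  maf <- mfdl:::with_seed(81, rare_skewed_maf(1e4))
  expect_true(all(maf > 0 & maf < 0.5))
  expect_lt(abs(mean(maf < 0.001) - 0.348), 0.05)
  expect_lt(abs(mean(maf < 0.01) - 0.691), 0.05)
  expect_lt(abs(mean(maf < 0.03) - 0.80), 0.05)
})

test_that("simulated genotypes are dosages with the requested frequency", {
  gm <- genotype_model(5000, 40, ld_rho = 0, maf_law = const_maf(0.5))
  g <- simulate_genotypes(gm, seed = 82)
  expect_true(all(g$values %in% c(0, 1, 2)))
  expect_true(!is.unsorted(g$positions01))
  # allele frequency near 0.5 and adjacent markers uncorrelated
  expect_lt(abs(mean(g$values) / 2 - 0.5), 0.02)
  adj <- vapply(1:39, function(j) cor(g$values[, j], g$values[, j + 1]),
                numeric(1))
  expect_lt(mean(abs(adj)), 0.05)
})

test_that("latent AR(1) correlation induces linkage disequilibrium", {
  adj_cor <- function(rho, seed) {
    g <- simulate_genotypes(genotype_model(300, 30, ld_rho = rho,
                                           maf_law = const_maf(0.3)),
                            seed = seed)
    mean(vapply(1:29, function(j)
      abs(cor(g$values[, j], g$values[, j + 1])), numeric(1)))
  }
  with_ld <- vapply(1:20, function(s) adj_cor(0.9, s), numeric(1))
  no_ld <- vapply(1:20, function(s) adj_cor(0, 100 + s), numeric(1))
  expect_gt(mean(with_ld), mean(no_ld))
  expect_gt(mean(with_ld), 0.3) # strong LD, not a marginal difference
})

test_that("expression draws are independent with the stated variance", {
  E <- simulate_expression(1e5, 2, variance = 0.5, seed = 83)
  expect_equal(dim(E), c(1e5L, 2L))
  expect_true(all(abs(apply(E, 2, var) - 0.5) < 0.01))
  expect_lt(abs(cov(E[, 1], E[, 2])), 0.02)
  expect_equal(dim(simulate_expression(10, 1, seed = 1)), c(10L, 1L))
})

test_that("linear effects match the brute-force triple loop", {
  set.seed(84)
  bs <- bspline_system(5, 7)
  for (r in 1:6) {
    vf <- rand_vf(5, 8)
    C <- matrix(rnorm(7 * 2), 7, 2)
    a <- runif(1, -3, 3)
    expect_equal(gen_linear_effect(vf, a, C, bs),
                 oracle_linear_effect(vf, a, C, bs), tolerance = 1e-10)
  }
  # zero effect size and the partition-of-unity single-marker reduction
  vf1 <- variant_function(matrix(2, 1, 1), 500)
  expect_equal(gen_linear_effect(vf1, 0, matrix(1, 7, 1), bs),
               matrix(0, 1, 1))
  expect_equal(gen_linear_effect(vf1, 1.3, matrix(1, 7, 1), bs),
               matrix(2 * 1.3, 1, 1), tolerance = 1e-12)
  # matrix (expression) inputs use their raw columns
  Xe <- matrix(rnorm(6), 3, 2); Ce <- matrix(rnorm(2), 2, 1)
  expect_equal(gen_linear_effect(Xe, 2, Ce), 2 * Xe %*% Ce)
})

test_that("nonlinear effects match the brute-force quadruple loop", {
  set.seed(85)
  for (r in 1:6) {
    vf <- rand_vf(4, 6)
    d1 <- runif(3, -pi, pi); d2 <- runif(3, -pi, pi)
    s_pts <- c(0.2, 0.5, 0.9)
    C <- matrix(rnorm(9), 3, 3)
    expect_equal(gen_nonlinear_effect(vf, d1, d2, C, s_pts),
                 oracle_nonlinear_effect(vf, d1, d2, C, s_pts),
                 tolerance = 1e-10)
  }
  # degenerate cases: zero amplitudes, zero genotypes
  vf <- rand_vf(3, 5, seed = 86)
  d <- rep(0.3, 3)
  expect_equal(gen_nonlinear_effect(vf, d, d, matrix(1, 1, 1), 0.5,
                                    c_l = c(0, 0, 0)),
               matrix(0, 3, 1))
  vf0 <- new_vf_for_test(matrix(0, 3, 5), vf$positions01)
  expect_equal(gen_nonlinear_effect(vf0, d, d, matrix(1, 1, 1), 0.5),
               matrix(0, 3, 1))
  # fractional powers of negative values are rejected
  vneg <- new_vf_for_test(matrix(-1, 2, 5), vf$positions01)
  expect_error(gen_nonlinear_effect(vneg, d, d, matrix(1, 1, 1), 0.5),
               "nonnegative")
})

test_that("the interaction term is the scaled product of the two effects", {
  set.seed(87)
  f1 <- matrix(rnorm(8), 4, 2); f2 <- matrix(rnorm(8), 4, 2)
  expect_equal(gen_interaction(f1, f2, 0), matrix(0, 4, 2))
  expect_equal(gen_interaction(matrix(0, 4, 2), f2, 3), matrix(0, 4, 2))
  expect_equal(gen_interaction(f1, f2, 1.7), 1.7 * f1 * f2)
  expect_error(gen_interaction(f1, matrix(0, 3, 2)), "identical dimensions")
  # scalar case: product of the two integral values computed independently
  vf <- rand_vf(5, 6, seed = 88)
  bs <- bspline_system(5, 7)
  Ca <- mfdl:::with_seed(89, matrix(rnorm(7), 7, 1))
  Cb <- mfdl:::with_seed(90, matrix(rnorm(7), 7, 1))
  fa <- gen_linear_effect(vf, 1.1, Ca, bs)
  fb <- gen_linear_effect(vf, -0.6, Cb, bs)
  int <- gen_interaction(fa, fb, 2)
  for (i in 1:5)
    expect_equal(int[i, 1], 2 * fa[i, 1] * fb[i, 1], tolerance = 1e-12)
})

test_that("datasets decompose exactly and reproduce bitwise from the seed", {
  for (rel in c("linear", "interaction", "nonlinear")) {
    spec <- scenario_spec(rel, "G-G", n = 30L, p1 = 20L)
    ds <- make_dataset(spec, 91)
    total <- ds$y1 + ds$y2
    if (!is.null(ds$Int)) total <- total + ds$Int
    total <- total + ds$eps
    expect_identical(ds$y, total)
    ds2 <- make_dataset(spec, 91)
    expect_identical(ds, ds2)
    expect_false(identical(ds, make_dataset(spec, 92)))
  }
})

test_that("noise realizations carry the configured variance", {
  spec <- scenario_spec("linear", "G-E", n = 1e4L, p1 = 5L, noise_var = 0.3)
  ds <- make_dataset(spec, 93)
  expect_lt(abs(var(as.vector(ds$eps)) - 0.3), 0.02)
  spec0 <- scenario_spec("interaction", "G-E", n = 25L, p1 = 10L,
                         noise_var = 0)
  ds0 <- make_dataset(spec0, 94)
  expect_identical(ds0$y, ds0$y1 + ds0$y2 + ds0$Int + ds0$eps)
  expect_true(all(ds0$eps == 0))
})

test_that("omics configurations produce the advertised modality shapes", {
  ge <- make_dataset(scenario_spec("linear", "G-E", n = 20L, p1 = 15L,
                                   p2 = 1L), 95)
  expect_s3_class(ge$modalities[[1]], "variant_function")
  expect_true(is.matrix(ge$modalities[[2]]))
  expect_equal(dim(ge$modalities[[2]]), c(20L, 1L))
  gg <- make_dataset(scenario_spec("linear", "G-G", n = 20L, p1 = 15L), 96)
  expect_s3_class(gg$modalities[[2]], "variant_function")
  expect_equal(ncol(gg$modalities[[2]]$values), 15L)
  # vector phenotype: 50 output columns driven by the s-grid
  vec <- make_dataset(scenario_spec("nonlinear", "G-E", n = 15L, p1 = 10L,
                                    phenotype_dim = 50L), 97)
  expect_equal(dim(vec$y), c(15L, 50L))
  expect_equal(vec$draws$s_points, seq(0, 1, length.out = 50))
})
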