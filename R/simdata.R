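#' Rare-skewed minor-allele-frequency sampler
#'
#' Samples minor allele frequencies from a law whose cumulative distribution
#' is piecewise linear on the log10 scale through the mass targets of a
#' sequenced human region heavily skewed to rare variants: 34.8% of markers
#' below MAF 0.001, 69.1% below 0.01 and 80% below 0.03, with support
#' [4.5e-4, 0.499].
#'
#' @param p number of markers.
#' @return Numeric vector of `p` MAFs in (0, 0.5).
#' @export
rare_skewed_maf <- function(p) {
  breaks <- log10(c(4.5e-4, 0.001, 0.01, 0.03, 0.499))
  mass <- c(0, 0.348, 0.691, 0.80, 1)
  u <- stats::runif(p)
  10^stats::approx(mass, breaks, xout = u, ties = "ordered")$y
}

#' Genotype simulation model
#'
#' Configures a latent-Gaussian haplotype simulator emulating a short
#' sequenced region: per-marker MAFs are drawn from `maf_law`, two
#' haplotypes per sample are generated by thresholding a latent AR(1)
#' Gaussian process across adjacent markers at each marker's MAF quantile
#' (inducing linkage disequilibrium), and genotype dosage is the haplotype
#' sum. Marker base-pair positions are drawn uniformly without replacement
#' from the region and sorted.
#'
#' @param n_samples number of individuals.
#' @param n_markers number of markers p.
#' @param ld_rho latent AR(1) correlation between adjacent markers, in
#'   [0, 1); 0 gives independent markers, values near 1 strong LD blocks.
#' @param region_bp region length in base pairs.
#' @param maf_law function of one argument (marker count) returning MAFs;
#'   defaults to [rare_skewed_maf()].
#' @return An object of class `genotype_model`.
#' @export
genotype_model <- function(n_samples, n_markers = 100L, ld_rho = 0.9,
                           region_bp = 30000L, maf_law = rare_skewed_maf) {
  if (ld_rho < 0 || ld_rho >= 1) stop("'ld_rho' must be in [0, 1)")
  if (n_markers > region_bp) stop("more markers than base pairs in region")
  structure(list(n_samples = as.integer(n_samples),
                 n_markers = as.integer(n_markers), ld_rho = ld_rho,
                 region_bp = as.integer(region_bp), maf_law = maf_law),
            class = "genotype_model")
}

#' Simulate genotypes with LD and a rare-skewed MAF spectrum
#'
#' @param model a [genotype_model()].
#' @param seed optional seed; if `NULL`, draws from the current RNG stream.
#' @param modality_id label for the resulting modality.
#' @return A [variant_function()] with dosage values in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(model, seed = NULL, modality_id = "genotype") {
  stopifnot(inherits(model, "genotype_model"))
  draw <- function() {
    n <- model$n_samples; p <- model$n_markers; rho <- model$ld_rho
    maf <- model$maf_law(p)
    thresh <- stats::qnorm(maf)
    Z <- matrix(0, 2L * n, p)
    Z[, 1L] <- stats::rnorm(2L * n)
    if (p > 1L) {
      innov_sd <- sqrt(1 - rho^2)
      for (j in 2:p)
        Z[, j] <- rho * Z[, j - 1L] + innov_sd * stats::rnorm(2L * n)
    }
    H <- sweep(Z, 2L, thresh, `<`) * 1
    G <- H[seq_len(n), , drop = FALSE] + H[n + seq_len(n), , drop = FALSE]
    pos <- sort(sample.int(model$region_bp, p))
    variant_function(G, positions_bp = pos, modality_id = modality_id)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate gene-expression measurements
#'
#' Independent normal entries with mean 0 and the given variance
#' (multivariate normal with diagonal covariance `variance * I`).
#'
#' @param n number of samples.
#' @param p2 number of expression features.
#' @param variance per-feature variance (default 0.5).
#' @param seed optional seed; if `NULL`, draws from the current RNG stream.
#' @return `n x p2` numeric matrix.
#' @export
simulate_expression <- function(n, p2 = 1L, variance = 0.5, seed = NULL) {
  stopifnot(p2 >= 1L, variance >= 0)
  draw <- function() matrix(stats::rnorm(n * p2, 0, sqrt(variance)), n, p2)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Linear phenotype effect of one modality
#'
#' \eqn{f_k = a_k \int_0^1 G_{ki}(t)\,B(t)\,C_k\,dt} for a functional
#' modality (the Dirac comb collapses the integral to [dirac_design()]
#' columns), or \eqn{a_k\, g_{ki}\, C_k} for a scalar/matrix modality.
#'
#' @param modality a [variant_function()] or numeric matrix.
#' @param a scalar effect size.
#' @param C coefficient matrix, `n_basis x d` (functional) or `p x d`
#'   (matrix input).
#' @param basis the generating [bspline_system()] (functional modalities).
#' @return `n x d` effect matrix.
#' @export
gen_linear_effect <- function(modality, a, C, basis = bspline_system(5L, 7L)) {
  C <- as.matrix(C)
  if (inherits(modality, "variant_function")) {
    Phi <- dirac_design(modality, basis)
    if (nrow(C) != ncol(Phi))
      stop("'C' must have n_basis = ", ncol(Phi), " rows")
    a * Phi %*% C
  } else {
    modality <- as.matrix(modality)
    if (nrow(C) != ncol(modality))
      stop("'C' must have p = ", ncol(modality), " rows")
    a * modality %*% C
  }
}

#' Nonlinear phenotype effect of one modality
#'
#' For each sample i and output point s,
#' \deqn{f(s) = \sum_{l=1}^{3} c_l \Big[\sum_j g_{ij}^{e_l}
#'   \cos(a_l t_j + d^{(1)}_l)\Big] \sin(a_l s + d^{(2)}_l),}
#' post-multiplied by the coefficient matrix `C`. The Dirac representation
#' again collapses the t-integral to a marker sum. A scalar phenotype uses
#' the single evaluation point s = 0.5.
#'
#' @param modality a [variant_function()] with nonnegative values (fractional
#'   powers of negative values are rejected).
#' @param d1,d2 length-3 phase vectors \eqn{d^{(1)}_l, d^{(2)}_l}.
#' @param C coefficient matrix, `length(s_points) x d`.
#' @param s_points output evaluation points (default the scalar convention
#'   0.5).
#' @param a_l,c_l,e fixed length-3 frequency, amplitude and exponent
#'   triples; defaults (2/3, -2, 2), (2/3, -2, 2) and (1/3, 3/2, 3).
#' @return `n x ncol(C)` effect matrix.
#' @export
gen_nonlinear_effect <- function(modality, d1, d2, C, s_points = 0.5,
                                 a_l = c(2 / 3, -2, 2),
                                 c_l = c(2 / 3, -2, 2),
                                 e = c(1 / 3, 3 / 2, 3)) {
  stopifnot(inherits(modality, "variant_function"),
            length(d1) == length(a_l), length(d2) == length(a_l),
            length(c_l) == length(a_l), length(e) == length(a_l))
  g <- modality$values
  frac <- e != round(e)
  if (any(frac) && any(g < 0))
    stop("fractional exponents require nonnegative modality values")
  tj <- modality$positions01
  C <- as.matrix(C)
  if (nrow(C) != length(s_points))
    stop("'C' must have length(s_points) = ", length(s_points), " rows")
  V <- matrix(0, nrow(g), length(s_points))
  for (l in seq_along(a_l)) {
    marker_sum <- drop((g^e[l]) %*% cos(a_l[l] * tj + d1[l]))
    V <- V + c_l[l] * outer(marker_sum, sin(a_l[l] * s_points + d2[l]))
  }
  V %*% C
}

#' Interaction effect between two modality effects
#'
#' The inner-product interaction \eqn{Int_i = c \langle f_1, f_2 \rangle},
#' which for the generated effects is the elementwise product of the two
#' effect matrices per output coordinate, scaled by `c`.
#'
#' @param f1,f2 `n x d` effect matrices.
#' @param c fixed scalar interaction coefficient.
#' @return `n x d` interaction matrix.
#' @export
gen_interaction <- function(f1, f2, c = 1) {
  f1 <- as.matrix(f1); f2 <- as.matrix(f2)
  if (!identical(dim(f1), dim(f2)))
    stop("'f1' and 'f2' must have identical dimensions")
  c * f1 * f2
}

#' Simulation scenario specification
#'
#' Describes one simulation scenario: the relationship between omics and
#' phenotype (linear, linear with an inner-product interaction, or
#' nonlinear), the omics configuration (genotype + expression, "G-E", or two
#' genotype regions, "G-G"), the phenotype dimension, and the noise
#' variance. Random coefficients (effect sizes `a_k`, coefficient matrices
#' `C_k`, nonlinear phases) are drawn per replicate inside
#' [make_dataset()]; the fixed triples of the nonlinear transformation are
#' part of the scenario definition.
#'
#' @param relationship "linear", "interaction" or "nonlinear".
#' @param omics "G-E" or "G-G".
#' @param phenotype_dim 1 for scalar phenotypes or the vector dimension.
#' @param noise_var variance of the additive Gaussian noise.
#' @param n sample size.
#' @param p1 number of markers of the (first) genotype modality.
#' @param p2 number of expression features (G-E only).
#' @param interaction_c fixed scalar coefficient of the interaction term.
#' @param ld_rho,region_bp genotype simulator parameters.
#' @param basis_order,n_basis generating B-spline system of the linear
#'   effects (fifth-order by default).
#' @param expr_variance expression variance (default 0.5).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(relationship = c("linear", "interaction",
                                           "nonlinear"),
                          omics = c("G-E", "G-G"), phenotype_dim = 1L,
                          noise_var = 0.3, n = 200L, p1 = 100L, p2 = 1L,
                          interaction_c = 1, ld_rho = 0.9,
                          region_bp = 30000L, basis_order = 5L,
                          n_basis = 7L, expr_variance = 0.5) {
  relationship <- match.arg(relationship)
  omics <- match.arg(omics)
  if (noise_var < 0) stop("'noise_var' must be nonnegative")
  structure(list(relationship = relationship, omics = omics,
                 phenotype_dim = as.integer(phenotype_dim),
                 noise_var = noise_var, n = as.integer(n),
                 p1 = as.integer(p1), p2 = as.integer(p2),
                 interaction_c = interaction_c, ld_rho = ld_rho,
                 region_bp = as.integer(region_bp),
                 basis_order = as.integer(basis_order),
                 n_basis = as.integer(n_basis),
                 expr_variance = expr_variance),
            class = "scenario_spec")
}

#' Generate a complete simulated dataset
#'
#' Draws the modalities, the per-replicate coefficients and the noise, and
#' assembles the phenotype \eqn{y = y_1 + y_2\,(+\,Int) + \epsilon}. All
#' signal components are stored, so the decomposition identity holds exactly
#' on every dataset, and the whole draw is reproducible from `seed`.
#'
#' Under the nonlinear relationship the nonlinear transformation (with its
#' fractional genotype powers) is applied to genotype modalities; an
#' expression modality, whose Gaussian values can be negative, contributes
#' through the linear transformation.
#'
#' @param spec a [scenario_spec()].
#' @param seed integer seed.
#' @return An object of class `sim_dataset` with fields `modalities`, `y`,
#'   `y1`, `y2`, `Int`, `eps`, `draws` (the realized coefficients), `spec`
#'   and `seed`.
#' @export
make_dataset <- function(spec, seed) {
  stopifnot(inherits(spec, "scenario_spec"))
  with_seed(seed, {
    n <- spec$n
    d <- spec$phenotype_dim
    basis <- bspline_system(spec$basis_order, spec$n_basis)
    s_points <- if (d == 1L) 0.5 else seq(0, 1, length.out = d)
    gm1 <- genotype_model(n, spec$p1, ld_rho = spec$ld_rho,
                          region_bp = spec$region_bp)
    mod1 <- simulate_genotypes(gm1, modality_id = "genotype1")
    mod2 <- if (spec$omics == "G-G") {
      simulate_genotypes(genotype_model(n, spec$p1, ld_rho = spec$ld_rho,
                                        region_bp = spec$region_bp),
                         modality_id = "genotype2")
    } else {
      simulate_expression(n, spec$p2, variance = spec$expr_variance)
    }
    modalities <- list(mod1, mod2)
    draws <- list(s_points = s_points)
    effects <- vector("list", 2L)
    for (k in 1:2) {
      m <- modalities[[k]]
      functional <- inherits(m, "variant_function")
      nonlinear_k <- spec$relationship == "nonlinear" && functional
      a_k <- stats::runif(1, -3, 3)
      if (nonlinear_k) {
        d1 <- stats::runif(3, -pi, pi)
        d2 <- stats::runif(3, -pi, pi)
        C_k <- matrix(stats::rnorm(length(s_points) * d), length(s_points), d)
        effects[[k]] <- gen_nonlinear_effect(m, d1, d2, C_k,
                                             s_points = s_points)
        draws[[paste0("m", k)]] <- list(kind = "nonlinear", a = a_k,
                                        d1 = d1, d2 = d2, C = C_k)
      } else {
        p_in <- if (functional) spec$n_basis else ncol(as.matrix(m))
        C_k <- matrix(stats::rnorm(p_in * d), p_in, d)
        effects[[k]] <- gen_linear_effect(m, a_k, C_k, basis = basis)
        draws[[paste0("m", k)]] <- list(kind = "linear", a = a_k, C = C_k)
      }
    }
    Int <- NULL
    if (spec$relationship == "interaction") {
      Int <- gen_interaction(effects[[1L]], effects[[2L]],
                             c = spec$interaction_c)
      draws$interaction_c <- spec$interaction_c
    }
    eps <- matrix(stats::rnorm(n * d, 0, sqrt(spec$noise_var)), n, d)
    y <- effects[[1L]] + effects[[2L]]
    if (!is.null(Int)) y <- y + Int
    y <- y + eps
    structure(list(modalities = modalities, y = y, y1 = effects[[1L]],
                   y2 = effects[[2L]], Int = Int, eps = eps, draws = draws,
                   spec = spec, seed = as.integer(seed)),
              class = "sim_dataset")
  })
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Simulated dataset: %s relationship, %s, n = %d, phenotype dim %d, noise var %g (seed %d)\n",
              x$spec$relationship, x$spec$omics, x$spec$n,
              x$spec$phenotype_dim, x$spec$noise_var, x$seed))
  invisible(x)
}
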