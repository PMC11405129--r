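#' Omics variant function
#'
#' Represents one omics modality as a Dirac comb over rescaled genomic
#' positions: sample i's function is \eqn{G_i(t) = \sum_j g_{ij}
#' \delta(t - t_j)}, where the marker positions are min-max rescaled from
#' base pairs to [0, 1]. Integrals of the comb against any smooth function
#' then collapse exactly to marker sums, which is what [dirac_design()]
#' exploits.
#'
#' @param values `n_samples x p` numeric matrix of marker values (genotype
#'   dosages 0/1/2 or continuous measurements). All entries must be finite.
#' @param positions_bp integer (or numeric) vector of length `p` with the
#'   markers' base-pair positions, sorted ascending and free of duplicates.
#'   A single marker is placed at 0.5 by convention.
#' @param modality_id optional label carried through to outputs.
#' @return An object of class `variant_function` with fields `values`,
#'   `positions01` and `modality_id`.
#' @examples
#' vf <- variant_function(matrix(c(0, 1, 2, 0, 0, 1), nrow = 2),
#'                        positions_bp = c(100, 200, 300))
#' vf$positions01 # 0, 0.5, 1
#' @export
variant_function <- function(values, positions_bp, modality_id = "omics") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (any(!is.finite(values))) stop("marker values must all be finite")
  p <- ncol(values)
  positions_bp <- as.numeric(positions_bp)
  if (length(positions_bp) != p)
    stop("length of 'positions_bp' (", length(positions_bp),
         ") does not match number of marker columns (", p, ")")
  if (is.unsorted(positions_bp, strictly = FALSE))
    stop("'positions_bp' must be sorted in ascending order")
  dup <- which(duplicated(positions_bp))
  if (length(dup) > 0L)
    stop("duplicate marker positions at base pairs: ",
         paste(unique(positions_bp[dup]), collapse = ", "),
         " (markers ", paste(dup, collapse = ", "), ")")
  positions01 <- if (p == 1L) {
    0.5
  } else {
    (positions_bp - positions_bp[1L]) / (positions_bp[p] - positions_bp[1L])
  }
  new_variant_function(values, positions01, modality_id,
                       positions_bp = positions_bp)
}

# internal constructor for callers that already hold positions on [0, 1]
new_variant_function <- function(values, positions01, modality_id = "omics",
                                 positions_bp = NULL) {
  structure(list(values = values, positions01 = as.numeric(positions01),
                 positions_bp = positions_bp, modality_id = modality_id),
            class = "variant_function")
}

#' @export
print.variant_function <- function(x, ...) {
  cat(sprintf("Omics variant function '%s': %d samples x %d markers on [0, 1]\n",
              x$modality_id, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @export
dim.variant_function <- function(x) dim(x$values)

#' Dirac design matrix of an omics variant function
#'
#' Exact value of \eqn{\int_0^1 G_i(t)\,\eta_l(t)\,dt} for every sample i and
#' basis function l. Because \eqn{G_i} is a Dirac comb the integral is the
#' marker sum \eqn{\sum_j g_{ij}\,\eta_l(t_j)}; no quadrature is involved.
#'
#' @param ovf a [variant_function()].
#' @param basis a [bspline_system()] on [0, 1].
#' @return `n_samples x n_basis` numeric matrix.
#' @export
dirac_design <- function(ovf, basis) {
  stopifnot(inherits(ovf, "variant_function"), inherits(basis, "basis_system"))
  ovf$values %*% eval_basis(basis, ovf$positions01)
}
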