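#' Mean squared error
#'
#' \eqn{MSE(Y, \hat Y) = \frac{1}{n}\sum_i \|y_i - \hat y_i\|^2}: squared
#' residual norms averaged over samples (not over phenotype coordinates).
#'
#' @param Y,Y_hat observed and predicted phenotypes, `n x d` matrices or
#'   length-n vectors.
#' @return Nonnegative scalar.
#' @export
mse <- function(Y, Y_hat) {
  Y <- as.matrix(Y); Y_hat <- as.matrix(Y_hat)
  if (!identical(dim(Y), dim(Y_hat)))
    stop("'Y' and 'Y_hat' must have identical dimensions")
  sum((Y - Y_hat)^2) / nrow(Y)
}

#' Mean absolute error
#'
#' Mean absolute deviation over all entries of the phenotype matrix.
#'
#' @inheritParams mse
#' @return Nonnegative scalar.
#' @export
mae <- function(Y, Y_hat) {
  Y <- as.matrix(Y); Y_hat <- as.matrix(Y_hat)
  if (!identical(dim(Y), dim(Y_hat)))
    stop("'Y' and 'Y_hat' must have identical dimensions")
  mean(abs(Y - Y_hat))
}

#' RV correlation coefficient
#'
#' The Robert-Escoufier RV coefficient between two data matrices,
#' \deqn{RV(Y, \hat Y) = \frac{tr(Y Y' \hat Y \hat Y')}
#'   {\sqrt{tr\{(Y Y')^2\}\, tr\{(\hat Y \hat Y')^2\}}},}
#' computed on column-mean-centered matrices. It generalizes the squared
#' Pearson correlation: for single-column inputs it equals \eqn{r^2}, and it
#' is invariant to nonzero rescaling of either matrix. Values lie in [0, 1].
#'
#' @inheritParams mse
#' @return Scalar in [0, 1].
#' @export
rv_coefficient <- function(Y, Y_hat) {
  Y <- as.matrix(Y); Y_hat <- as.matrix(Y_hat)
  if (nrow(Y) != nrow(Y_hat))
    stop("'Y' and 'Y_hat' must have the same number of rows")
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  Hc <- scale(Y_hat, center = TRUE, scale = FALSE)
  sy <- sqrt(sum(crossprod(Yc)^2))
  sh <- sqrt(sum(crossprod(Hc)^2))
  if (sy == 0 || sh == 0)
    stop("RV coefficient undefined: a matrix is constant (zero after centering)")
  # tr(YY' HH') = ||Y'H||_F^2; tr((YY')^2) = ||Y'Y||_F^2
  sum(crossprod(Yc, Hc)^2) / (sy * sh)
}

#' One evaluation-result row
#'
#' @param method method label.
#' @param split "train" or "test".
#' @param Y,Y_hat observed and predicted phenotypes.
#' @param replicate_id,seed bookkeeping fields.
#' @param lambda penalty used by the fit (or `NA`).
#' @return One-row data frame with mse, mae and rv columns.
#' @export
eval_result <- function(method, split, Y, Y_hat, replicate_id = NA_integer_,
                        seed = NA_integer_, lambda = NA_real_) {
  data.frame(method = method, split = split,
             mse = mse(Y, Y_hat), mae = mae(Y, Y_hat),
             rv = rv_coefficient(Y, Y_hat),
             n = nrow(as.matrix(Y)), replicate_id = replicate_id,
             seed = seed, lambda = lambda)
}
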