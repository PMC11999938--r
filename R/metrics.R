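#' Root-mean-square error, in percent of normalized force
#'
#' `RMSE = sqrt(mean((y - yhat)^2)) * 100`, the loss and headline metric
#' of the force estimator. Since forces are min-max normalized to
#' `[0, 1]`, the value reads directly as a percentage of the force range.
#'
#' @param y_true measured (normalized) force targets.
#' @param y_pred estimated force targets, same length.
#' @return nonnegative scalar, in percent.
#' @examples
#' rmse_pct(c(0, 0), c(0.1, 0.1)) # 10
#' @export
rmse_pct <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_named("length_mismatch", "y_true and y_pred lengths differ")
  }
  stopifnot(length(y_true) >= 1L)
  sqrt(mean((y_true - y_pred)^2)) * 100
}

#' Goodness of fit between estimated and measured force
#'
#' The squared Pearson correlation,
#' `R^2 = (sum((x - xbar) (y - ybar)))^2 /
#'        (sum((x - xbar)^2) sum((y - ybar)^2))`,
#' which lies in `[0, 1]` by Cauchy-Schwarz. Undefined (error) when
#' either input has zero variance.
#'
#' @param x estimated force.
#' @param y measured force, same length, `n >= 2`.
#' @return scalar in `[0, 1]`.
#' @export
r_squared <- function(x, y) {
  if (length(x) != length(y)) {
    stop_named("length_mismatch", "x and y lengths differ")
  }
  stopifnot(length(x) >= 2L)
  xd <- x - mean(x)
  yd <- y - mean(y)
  sxx <- sum(xd^2)
  syy <- sum(yd^2)
  if (sxx == 0 || syy == 0) {
    stop_named("zero_variance", "R^2 undefined for zero-variance input")
  }
  sum(xd * yd)^2 / (sxx * syy)
}
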