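#' Lower developmental threshold from linear-model coefficients
#'
#' For the linear development-rate model \eqn{D(T) = a + b T}, the lower
#' developmental threshold is its x-intercept, \eqn{T_b = -a/b}: the
#' temperature below which development is theoretically not possible.
#'
#' @param a Intercept of the linear rate model, 1/day.
#' @param b Slope of the linear rate model, 1/(day \eqn{\cdot} degree C).
#'   Must be non-zero.
#' @return Lower threshold \eqn{T_b}, degrees Celsius.
#' @examples
#' linear_lower_threshold(a = -3.52e-2, b = 2.94e-3)  # 11.97
#' @export
linear_lower_threshold <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1, is.finite(a), is.finite(b))
  if (b == 0) stop("lower threshold is undefined when the slope 'b' is zero")
  -a / b
}

#' Degree-day requirement from the linear-model slope
#'
#' Under the linear rate model \eqn{D(T) = a + b T}, one degree above the
#' threshold sustained for one day advances development by \eqn{b}; the
#' thermal constant needed to complete development is therefore
#' \eqn{DD = 1/b} degree-days.
#'
#' @inheritParams linear_lower_threshold
#' @return Degree-day requirement, degree-days. Requires `b > 0`.
#' @examples
#' linear_degree_days(b = 2.94e-3)  # 340.1
#' @export
linear_degree_days <- function(b) {
  stopifnot(length(b) == 1, is.finite(b))
  if (b <= 0)
    stop("degree-day requirement is undefined for a non-positive slope 'b'")
  1 / b
}

#' Coefficient of determination
#'
#' Plain (unadjusted) \eqn{R^2 = 1 - SS_{res}/SS_{tot}} with the total sum of
#' squares centred on the observed mean. The same formula is used for linear
#' and nonlinear fits, so a badly specified model can return a negative value.
#' Optional case weights enter both sums of squares (the mean is then the
#' weighted mean).
#'
#' @param observed Observed rates, 1/day.
#' @param predicted Model-predicted rates, same length.
#' @param weights Optional non-negative case weights, same length.
#' @return \eqn{R^2}, dimensionless, at most 1.
#' @examples
#' r_squared(c(0.01, 0.02, 0.03), c(0.012, 0.02, 0.028))  # 0.96
#' @export
r_squared <- function(observed, predicted, weights = NULL) {
  stopifnot(is.numeric(observed), is.numeric(predicted),
            length(observed) == length(predicted))
  if (length(observed) < 2)
    stop("at least two observations are needed to compute R-squared")
  if (is.null(weights)) weights <- rep(1, length(observed))
  stopifnot(length(weights) == length(observed), all(weights >= 0))
  mu <- sum(weights * observed) / sum(weights)
  ss_tot <- sum(weights * (observed - mu)^2)
  if (ss_tot == 0)
    stop("R-squared is undefined when all observed rates are identical")
  ss_res <- sum(weights * (observed - predicted)^2)
  1 - ss_res / ss_tot
}
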