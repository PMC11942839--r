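#' Briere development-rate function
#'
#' Evaluates the Briere thermal performance curve
#' \deqn{D(T) = n \, T \, (T - T_b) \, (T_L - T)^{1/m}}
#' which is zero at the lower threshold \eqn{T_b} and the upper threshold
#' \eqn{T_L}, positive between them (for `n_coef > 0`), and has an asymmetric
#' peak skewed towards \eqn{T_L}. Temperatures outside \eqn{[T_b, T_L]} return
#' a rate of exactly 0: development is theoretically not possible there.
#'
#' @param temp Temperature(s), degrees Celsius. Vectorised.
#' @param n_coef Scale coefficient \eqn{n} (empirical, no biological meaning).
#' @param t_b Lower developmental threshold, degrees Celsius.
#' @param t_l Upper developmental threshold, degrees Celsius. Must exceed `t_b`.
#' @param m Shape exponent \eqn{m > 0} (empirical).
#'
#' @return Numeric vector of development rates (1/day), same length as `temp`.
#' @seealso [briere_optimum()] for the closed-form peak, [devrate()] to fit
#'   the curve to data.
#' @examples
#' briere_rate(25, n_coef = 5.74e-5, t_b = 12.57, t_l = 33.0, m = 2.4)
#' briere_rate(c(12.57, 33.0), 5.74e-5, 12.57, 33.0, 2.4)  # both roots: 0
#' @export
briere_rate <- function(temp, n_coef, t_b, t_l, m) {
  stopifnot(is.numeric(temp), length(n_coef) == 1, length(t_b) == 1,
            length(t_l) == 1, length(m) == 1)
  if (!is.finite(m) || m <= 0) stop("'m' must be a positive number")
  if (!is.finite(t_b) || !is.finite(t_l) || t_l <= t_b)
    stop("'t_l' must be strictly greater than 't_b'")
  rate <- numeric(length(temp))
  inside <- !is.na(temp) & temp >= t_b & temp <= t_l
  Ti <- temp[inside]
  rate[inside] <- n_coef * Ti * (Ti - t_b) * (t_l - Ti)^(1 / m)
  rate[is.na(temp)] <- NA_real_
  rate
}

#' Optimum temperature of the Briere curve
#'
#' Closed-form maximiser of the Briere development-rate function on
#' \eqn{[T_b, T_L]}. Setting the derivative of
#' \eqn{T (T - T_b) (T_L - T)^{1/m}} to zero gives the quadratic
#' \eqn{(2m+1) T^2 - (2 m T_L + (m+1) T_b) T + m T_b T_L = 0}, whose larger
#' root is the interior maximum:
#' \deqn{T_{opt} = \frac{2 m T_L + (m+1) T_b +
#'   \sqrt{4 m^2 T_L^2 + (m+1)^2 T_b^2 - 4 m^2 T_b T_L}}{4m + 2}}
#'
#' The scale coefficient \eqn{n} does not affect the location of the peak.
#'
#' @inheritParams briere_rate
#' @return Optimum temperature, degrees Celsius; always in `(t_b, t_l)`.
#' @examples
#' briere_optimum(t_b = 12.57, t_l = 33.0, m = 2.4)  # ~28.70
#' briere_optimum(t_b = 0, t_l = 33, m = 1)          # 2/3 * t_l = 22
#' @export
briere_optimum <- function(t_b, t_l, m) {
  stopifnot(length(t_b) == 1, length(t_l) == 1, length(m) == 1)
  if (!is.finite(m) || m <= 0) stop("'m' must be a positive number")
  if (!is.finite(t_b) || !is.finite(t_l) || t_l <= t_b)
    stop("'t_l' must be strictly greater than 't_b'")
  disc <- 4 * m^2 * t_l^2 + (m + 1)^2 * t_b^2 - 4 * m^2 * t_b * t_l
  (2 * m * t_l + (m + 1) * t_b + sqrt(disc)) / (4 * m + 2)
}
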