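#' Accumulate degree-days over a daily temperature series
#'
#' Rectangle-method thermal summation above a lower developmental threshold:
#' each day contributes \eqn{\max(T_i - T_b, 0) \cdot \Delta t} degree-days,
#' where \eqn{T_i} is the daily mean temperature. Days at or below the
#' threshold contribute exactly zero — development never runs backwards.
#' There is no upper-threshold cutoff by default (the sum subtracts only
#' \eqn{T_b}); an optional horizontal cutoff caps the temperature used in
#' the increment at `t_cap` for users who want it.
#'
#' @param series A `"temperature_series"` data frame (see
#'   [temperature_series()] / [read_temperature_series()]).
#' @param t_b Lower developmental threshold, deg C.
#' @param delta_t Integration step in days, usually 1 (daily means).
#' @param t_cap Optional horizontal upper cutoff, deg C (`NULL`, the
#'   default, disables it).
#' @return A data frame of class `"degree_day_trace"` with columns `day`,
#'   `t_mean`, `increment` and `cumulative`, and attributes `t_b` and
#'   `delta_t`.
#' @examples
#' s <- temperature_series(1:10, rep(25, 10))
#' accumulate_degree_days(s, t_b = 11.97)
#' @export
accumulate_degree_days <- function(series, t_b, delta_t = 1, t_cap = NULL) {
  stopifnot(inherits(series, "temperature_series"))
  if (nrow(series) == 0) stop("temperature series is empty")
  stopifnot(length(t_b) == 1, is.finite(t_b), delta_t > 0)
  t_eff <- if (is.null(t_cap)) series$t_mean else pmin(series$t_mean, t_cap)
  inc <- pmax(t_eff - t_b, 0) * delta_t
  out <- data.frame(day = series$day, t_mean = series$t_mean,
                    increment = inc, cumulative = cumsum(inc))
  structure(out, t_b = t_b, delta_t = delta_t,
            class = c("degree_day_trace", "data.frame"))
}

#' Predict the emergence day from degree-day accumulation
#'
#' Returns the first day on which the cumulative degree-day sum above the
#' lower threshold reaches the degree-day requirement of the life stage, or
#' `NA` if the requirement is never met within the series.
#'
#' @inheritParams accumulate_degree_days
#' @param dd_requirement Degree-day requirement (thermal constant), > 0.
#' @return Integer day index, or `NA_integer_` if emergence is not reached.
#' @examples
#' s <- temperature_series(1:40, rep(25, 40))
#' predict_emergence(s, t_b = 11.97, dd_requirement = 340.1)  # day 27
#' @export
predict_emergence <- function(series, t_b, dd_requirement, delta_t = 1,
                              t_cap = NULL) {
  stopifnot(length(dd_requirement) == 1, is.finite(dd_requirement),
            dd_requirement > 0)
  trace <- accumulate_degree_days(series, t_b, delta_t, t_cap)
  hit <- which(trace$cumulative >= dd_requirement)
  if (length(hit) == 0) NA_integer_ else trace$day[hit[1]]
}

#' @export
print.degree_day_trace <- function(x, ...) {
  cat(sprintf("Degree-day trace: %d day(s), Tb = %g degC, delta_t = %g d\n",
              nrow(x), attr(x, "t_b"), attr(x, "delta_t")))
  cat(sprintf("Final cumulative sum: %.2f degree-days\n",
              x$cumulative[nrow(x)]))
  NextMethod()
}

#' Write a degree-day trace and emergence summary to CSV
#'
#' @param trace A `"degree_day_trace"` from [accumulate_degree_days()].
#' @param path Output CSV path.
#' @param dd_requirement Optional degree-day requirement; when given, a
#'   one-line emergence summary is appended as a trailing comment.
#' @return `path`, invisibly.
#' @export
write_degree_day_trace <- function(trace, path, dd_requirement = NULL) {
  stopifnot(inherits(trace, "degree_day_trace"))
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE, quote = FALSE)
  if (!is.null(dd_requirement)) {
    hit <- which(trace$cumulative >= dd_requirement)
    msg <- if (length(hit) == 0)
      sprintf("# emergence: not reached (requirement %g DD, accumulated %.2f)",
              dd_requirement, trace$cumulative[nrow(trace)])
    else
      sprintf("# emergence: day %d (requirement %g DD)",
              trace$day[hit[1]], dd_requirement)
    cat(msg, "\n", sep = "", file = path, append = TRUE)
  }
  invisible(path)
}
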