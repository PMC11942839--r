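#' @export
print.devrate <- function(x, digits = 4, ...) {
  cat(switch(x$model,
             linear = "Linear development-rate model D(T) = a + b*T\n",
             briere = "Briere development-rate model D(T) = n*T*(T - Tb)*(TL - T)^(1/m)\n"))
  cat("Coefficients:\n")
  print(signif(x$coefficients, digits))
  cat("R-squared:", format(signif(x$r.squared, digits)),
      " n =", x$n_obs, "observations at", x$n_temps, "temperatures\n")
  if (x$model == "linear" && is.finite(x$t_b))
    cat(sprintf("Lower threshold Tb = %s degC; degree-day requirement = %s DD\n",
                format(signif(x$t_b, digits)), format(signif(x$dd, digits))))
  if (x$model == "briere")
    cat(sprintf("Thresholds: Tb = %s, TL = %s degC; optimum Topt = %s degC\n",
                format(signif(x$t_b, digits)), format(signif(x$t_l, digits)),
                format(signif(unname(x$t_opt), digits))))
  invisible(x)
}

#' @export
summary.devrate <- function(object, ...) {
  ct <- cbind(Estimate = object$coefficients,
              `Approx. SE` = object$se)
  out <- list(model = object$model, coefficients = ct,
              r.squared = object$r.squared, n_obs = object$n_obs,
              n_temps = object$n_temps,
              derived = switch(object$model,
                linear = c(t_b = object$t_b, dd = object$dd),
                briere = c(t_b = object$t_b, t_l = object$t_l,
                           t_opt = unname(object$t_opt))),
              convergence = object$convergence,
              at_boundary = object$at_boundary,
              rss = object$rss)
  class(out) <- "summary.devrate"
  out
}

#' @export
print.summary.devrate <- function(x, digits = 4, ...) {
  cat("Model:", x$model, "\n\nCoefficients (approximate standard errors):\n")
  print(signif(x$coefficients, digits))
  cat("\nDerived quantities:\n")
  print(signif(x$derived, digits))
  cat("\nR-squared:", format(signif(x$r.squared, digits)),
      " n =", x$n_obs, "at", x$n_temps, "temperatures\n")
  if (identical(x$model, "briere")) {
    cat("Residual sum of squares:", format(signif(x$rss, digits)), "\n")
    if (isTRUE(x$at_boundary))
      cat("Note: solution lies on a search-bound boundary.\n")
  }
  invisible(x)
}

#' @export
coef.devrate <- function(object, ...) object$coefficients

#' @export
fitted.devrate <- function(object, ...) object$fitted.values

#' @export
residuals.devrate <- function(object, ...) object$residuals

#' Predict development rates (or times) from a fitted model
#'
#' @param object A fitted `"devrate"` model.
#' @param newdata Data frame with a `temperature` column, or a numeric vector
#'   of temperatures. Defaults to the temperatures used in fitting.
#' @param type `"rate"` (1/day) or `"time"` (days, the reciprocal; `Inf`
#'   where the predicted rate is zero or negative).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.devrate <- function(object, newdata = NULL,
                            type = c("rate", "time"), ...) {
  type <- match.arg(type)
  temps <- if (is.null(newdata)) object$observations$temperature
           else if (is.numeric(newdata)) newdata
           else newdata$temperature
  cf <- object$coefficients
  rate <- switch(object$model,
    linear = unname(cf["a"] + cf["b"] * temps),
    briere = briere_rate(temps, cf["n_coef"], cf["t_b"], cf["t_l"], cf["m"]))
  if (type == "rate") return(rate)
  ifelse(rate > 0, 1 / rate, Inf)
}

#' Simulate development rates from a fitted model
#'
#' Draws Gaussian responses around the fitted curve at the observed
#' temperatures, with the residual standard deviation of the fit (the
#' conventional parametric response simulation, as in [stats::simulate()]
#' for linear models). Negative draws are truncated at zero, since a
#' development rate cannot be negative.
#'
#' @param object A fitted `"devrate"` model.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return Data frame with one column per simulation.
#' @export
simulate.devrate <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- object$fitted.values
  sd <- if (!is.null(object$sigma)) object$sigma else {
    dof <- max(object$n_obs - length(object$coefficients), 1)
    sqrt(object$rss / dof)
  }
  out <- as.data.frame(replicate(nsim, pmax(stats::rnorm(length(mu), mu, sd), 0)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted development-rate curve over the observations
#'
#' @param x A fitted `"devrate"` model.
#' @param from,to Temperature range for the curve; defaults to the observed
#'   range extended to the thresholds where defined.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.devrate <- function(x, from = NULL, to = NULL, ...) {
  obs <- x$observations
  if (is.null(from))
    from <- min(obs$temperature, if (is.finite(x$t_b)) x$t_b else Inf)
  if (is.null(to))
    to <- max(obs$temperature, if (!is.null(x$t_l)) x$t_l else -Inf)
  tt <- seq(from, to, length.out = 200)
  graphics::plot(obs$temperature, obs$rate,
                 xlab = "Temperature (degC)",
                 ylab = "Development rate (1/day)",
                 xlim = c(from, to), ...)
  graphics::lines(tt, predict(x, tt))
  if (is.finite(x$t_b)) graphics::abline(v = x$t_b, lty = 3)
  if (!is.null(x$t_l)) graphics::abline(v = x$t_l, lty = 3)
  invisible(x)
}
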