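#' Fit a temperature-dependent development-rate model
#'
#' Fits either the linear degree-day model \eqn{D(T) = a + bT} or the Briere
#' curve \eqn{D(T) = n T (T - T_b) (T_L - T)^{1/m}} to development-rate
#' observations by (weighted) least squares, and derives the biological
#' quantities each model supports:
#'
#' * linear: lower threshold \eqn{T_b = -a/b} and degree-day requirement
#'   \eqn{DD = 1/b} (reported only when the slope is positive);
#' * Briere: lower and upper thresholds \eqn{T_b, T_L} and the optimum
#'   temperature \eqn{T_{opt}} from [briere_optimum()].
#'
#' The linear model is an ordinary least-squares fit ([stats::lm()]). The
#' Briere least-squares surface is multimodal in \eqn{(T_b, T_L, m)}, so the
#' fit uses a deterministic multistart: the scale coefficient \eqn{n} is
#' profiled out analytically (for fixed thresholds and shape the model is
#' linear in \eqn{n}), and the remaining three parameters are refined with
#' box-constrained quasi-Newton ([stats::optim()] `"L-BFGS-B"`) from every
#' node of an evenly spaced grid of starting values over the bounds. The
#' lowest residual sum of squares wins; ties go to the earliest start in grid
#' order, so repeated fits are bit-reproducible.
#'
#' @param x A formula such as `rate ~ temperature` (with `data`), or a data
#'   frame of observations with columns `temperature` and `rate` (e.g. a
#'   `"rate_obs"` frame from [rates_from_records()]).
#' @param data Data frame in which to evaluate `x` when it is a formula.
#' @param model `"linear"` or `"briere"`.
#' @param weights Optional non-negative case weights. Defaults to the
#'   `weight` column of a `"rate_obs"` input, else 1.
#' @param bounds Box constraints for the Briere search, from
#'   [briere_bounds()]. Data-dependent defaults: \eqn{T_b} in `[0,` min
#'   observed temperature`)`, \eqn{T_L} in `(`max observed temperature`, 45]`,
#'   \eqn{m} in `[0.3, 6]`.
#' @param n_starts Integer vector of length 3: number of starting values per
#'   parameter `(t_b, t_l, m)`. Default `c(5, 5, 5)` = 125 starts.
#'
#' @return An object of class `c("devrate_linear", "devrate")` or
#'   `c("devrate_briere", "devrate")` with `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `plot` and `simulate` methods.
#' @examples
#' lt <- parasitoid_devtimes()
#' obs <- rates_from_records(lt)
#' cc_f <- obs[obs$species == "C. cunea" & obs$sex == "female", ]
#' fit <- devrate(cc_f, model = "briere")
#' coef(fit)
#' predict(fit, newdata = data.frame(temperature = 18:30))
#' @export
devrate <- function(x, data = NULL, model = c("linear", "briere"),
                    weights = NULL, bounds = NULL, n_starts = c(5, 5, 5)) {
  model <- match.arg(model)
  cl <- match.call()
  if (inherits(x, "formula")) {
    mf <- stats::model.frame(x, data = data)
    obs <- data.frame(rate = mf[[1]], temperature = mf[[2]])
  } else {
    stopifnot(is.data.frame(x), all(c("temperature", "rate") %in% names(x)))
    obs <- x
    if (is.null(weights) && "weight" %in% names(x)) weights <- x$weight
  }
  if (is.null(weights)) weights <- rep(1, nrow(obs))
  stopifnot(length(weights) == nrow(obs), all(weights >= 0))
  if (any(!is.finite(obs$temperature)) || any(!is.finite(obs$rate)))
    stop("temperatures and rates must be finite")
  if (any(obs$rate < 0)) stop("development rates must be non-negative")
  fit <- switch(model,
                linear = .fit_linear(obs, weights),
                briere = .fit_briere(obs, weights, bounds, n_starts))
  fit$call <- cl
  fit
}

.fit_linear <- function(obs, w) {
  n_temps <- length(unique(obs$temperature))
  if (n_temps < 2)
    stop("the linear model needs at least 2 distinct temperatures")
  lmfit <- stats::lm(rate ~ temperature, data = obs, weights = w)
  cf <- stats::coef(lmfit)
  a <- unname(cf[1]); b <- unname(cf[2])
  # summary.lm warns on zero-residual data; degenerate fits are handled below
  se <- suppressWarnings(sqrt(diag(stats::vcov(lmfit))))
  fitted <- as.numeric(stats::fitted(lmfit))
  r2 <- tryCatch(r_squared(obs$rate, fitted, w), error = function(e) NA_real_)
  if (b > 0) {
    t_b <- linear_lower_threshold(a, b)
    dd <- linear_degree_days(b)
  } else {
    warning("non-positive slope: lower threshold and degree-day requirement ",
            "are undefined")
    t_b <- NA_real_
    dd <- NA_real_
  }
  structure(list(
    model = "linear",
    coefficients = c(a = a, b = b),
    se = c(a = unname(se[1]), b = unname(se[2])),
    r.squared = r2,
    t_b = t_b, dd = dd,
    n_obs = nrow(obs), n_temps = n_temps,
    observations = obs, weights = w,
    fitted.values = fitted,
    residuals = obs$rate - fitted,
    sigma = stats::sigma(lmfit)
  ), class = c("devrate_linear", "devrate"))
}

#' Bounds for the Briere parameter search
#'
#' Builds the box constraints used by the multistart Briere fit. Thresholds
#' must bracket the observed developing window, so by default the lower
#' threshold is searched below the coldest temperature with development and
#' the upper threshold above the warmest, with 45 deg C as a biologically
#' safe ceiling. Any component can be overridden.
#'
#' @param t_b Length-2 range for the lower threshold, deg C.
#' @param t_l Length-2 range for the upper threshold, deg C.
#' @param m Length-2 range for the shape exponent.
#' @return A list of class `"briere_bounds"`; `NULL` entries are resolved
#'   from the data at fit time.
#' @export
briere_bounds <- function(t_b = NULL, t_l = NULL, m = c(0.3, 6)) {
  for (nm in c("t_b", "t_l", "m")) {
    v <- get(nm)
    if (!is.null(v) && (length(v) != 2 || v[1] >= v[2]))
      stop("'", nm, "' bounds must be an increasing length-2 vector")
  }
  structure(list(t_b = t_b, t_l = t_l, m = m), class = "briere_bounds")
}

.resolve_bounds <- function(bounds, temps) {
  if (is.null(bounds)) bounds <- briere_bounds()
  stopifnot(inherits(bounds, "briere_bounds"))
  eps <- 1e-6
  if (is.null(bounds$t_b)) bounds$t_b <- c(0, min(temps) - eps)
  if (is.null(bounds$t_l)) bounds$t_l <- c(max(temps) + eps, 45)
  if (bounds$t_b[2] >= bounds$t_l[1])
    stop("threshold bounds must keep t_b below t_l")
  bounds
}

# Profiled residual sum of squares: for fixed (t_b, t_l, m) the model is
# linear in n, so the optimal n has a closed form.
.briere_profile <- function(theta, temps, rates, w) {
  g <- numeric(length(temps))
  inside <- temps > theta[1] & temps < theta[2]
  Ti <- temps[inside]
  g[inside] <- Ti * (Ti - theta[1]) * (theta[2] - Ti)^(1 / theta[3])
  denom <- sum(w * g^2)
  n_hat <- if (denom > 0) sum(w * rates * g) / denom else 0
  rss <- sum(w * (rates - n_hat * g)^2)
  list(rss = rss, n_coef = n_hat)
}

.fit_briere <- function(obs, w, bounds, n_starts) {
  n_temps <- length(unique(obs$temperature))
  if (n_temps < 3)
    stop("the Briere model needs at least 3 distinct temperatures")
  if (n_temps == 3)
    warning("only 3 distinct temperatures for a 4-parameter model: ",
            "the fit is underdetermined; parameters are not uniquely ",
            "identified")
  stopifnot(length(n_starts) == 3, all(n_starts >= 1))
  b <- .resolve_bounds(bounds, obs$temperature)
  lower <- c(b$t_b[1], b$t_l[1], b$m[1])
  upper <- c(b$t_b[2], b$t_l[2], b$m[2])
  mid <- function(rng, k) rng[1] + (seq_len(k) - 0.5) / k * (rng[2] - rng[1])
  starts <- expand.grid(t_b = mid(b$t_b, n_starts[1]),
                        t_l = mid(b$t_l, n_starts[2]),
                        m = mid(b$m, n_starts[3]))
  fn <- function(theta)
    .briere_profile(theta, obs$temperature, obs$rate, w)$rss
  best <- NULL
  n_converged <- 0L
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(as.numeric(starts[i, ]), fn, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) n_converged <- n_converged + 1L
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("Briere fit failed: no multistart converged; check bounds and data")
  theta <- best$par
  prof <- .briere_profile(theta, obs$temperature, obs$rate, w)
  cf <- c(n_coef = prof$n_coef, t_b = theta[1], t_l = theta[2], m = theta[3])
  at_boundary <- any(abs(theta - lower) < 1e-8 * pmax(1, abs(lower))) ||
    any(abs(theta - upper) < 1e-8 * pmax(1, abs(upper)))
  if (at_boundary)
    warning("best Briere fit lies on a search-bound boundary; ",
            "consider widening the bounds")
  fitted <- briere_rate(obs$temperature, cf["n_coef"], cf["t_b"],
                        cf["t_l"], cf["m"])
  r2 <- tryCatch(r_squared(obs$rate, fitted, w), error = function(e) NA_real_)
  structure(list(
    model = "briere",
    coefficients = cf,
    se = .briere_se(cf, obs, w, prof$rss),
    r.squared = r2,
    t_b = unname(cf["t_b"]), t_l = unname(cf["t_l"]),
    t_opt = briere_optimum(cf["t_b"], cf["t_l"], cf["m"]),
    rss = prof$rss,
    n_obs = nrow(obs), n_temps = n_temps,
    observations = obs, weights = w,
    fitted.values = as.numeric(fitted),
    residuals = obs$rate - as.numeric(fitted),
    convergence = n_converged > 0,
    n_starts = nrow(starts),
    at_boundary = at_boundary,
    bounds = b
  ), class = c("devrate_briere", "devrate"))
}

# Approximate standard errors from the Gauss-Newton covariance
# sigma^2 (J' W J)^-1 with a central-difference Jacobian; NA when the fit
# leaves no residual degrees of freedom.
.briere_se <- function(cf, obs, w, rss) {
  p <- length(cf)
  dof <- nrow(obs) - p
  se <- rep(NA_real_, p)
  names(se) <- names(cf)
  if (dof <= 0 || rss <= 0) return(se)
  f <- function(par) briere_rate(obs$temperature, par[1], par[2], par[3], par[4])
  J <- matrix(0, nrow(obs), p)
  h <- pmax(abs(cf), 1e-4) * 1e-5
  for (j in seq_len(p)) {
    up <- dn <- as.numeric(cf)
    up[j] <- up[j] + h[j]; dn[j] <- dn[j] - h[j]
    Jj <- tryCatch((f(up) - f(dn)) / (2 * h[j]), error = function(e) NULL)
    if (is.null(Jj)) return(se)
    J[, j] <- Jj
  }
  sigma2 <- rss / dof
  JtWJ <- crossprod(J * sqrt(w))
  cov <- tryCatch(sigma2 * solve(JtWJ), error = function(e) NULL)
  if (!is.null(cov)) {
    d <- diag(cov)
    se[d >= 0] <- sqrt(d[d >= 0])
  }
  se
}
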