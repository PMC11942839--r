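#' Fit both rate models to every species-sex group
#'
#' Splits rate observations by species and sex (the usual reporting unit of
#' constant-temperature rearing studies) and fits the requested models to
#' each group. Groups that fail a model's preconditions are reported as
#' failures, not fatal.
#'
#' @param obs A `"rate_obs"` data frame (see [rates_from_records()]).
#' @param models Character vector among `"linear"`, `"briere"`.
#' @param n_starts Multistart grid for Briere fits, see [devrate()].
#' @return A list of class `"devrate_groups"`: `fits` (nested list
#'   `[[species.sex]][[model]]`), `failures` (data frame of group, model,
#'   message) and `summary` — one row per group x model with parameters,
#'   derived thresholds, degree-days, optimum and R-squared.
#' @examples
#' fits <- fit_groups(rates_from_records(parasitoid_devtimes()))
#' fits$summary
#' @export
fit_groups <- function(obs, models = c("linear", "briere"),
                       n_starts = c(5, 5, 5)) {
  stopifnot(is.data.frame(obs), all(c("temperature", "rate") %in% names(obs)))
  models <- match.arg(models, several.ok = TRUE)
  if (!"species" %in% names(obs)) obs$species <- "all"
  if (!"sex" %in% names(obs)) obs$sex <- "unknown"
  fits <- list()
  failures <- list()
  rows <- list()
  for (grp in split(obs, list(obs$species, obs$sex), drop = TRUE)) {
    key <- paste(grp$species[1], grp$sex[1], sep = ".")
    for (model in models) {
      fit <- tryCatch(
        suppressWarnings(devrate(grp, model = model, n_starts = n_starts)),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failures[[length(failures) + 1]] <- data.frame(
          group = key, model = model, message = conditionMessage(fit))
        next
      }
      fits[[key]][[model]] <- fit
      cf <- coef(fit)
      rows[[length(rows) + 1]] <- data.frame(
        species = grp$species[1], sex = grp$sex[1], model = model,
        a = if (model == "linear") unname(cf["a"]) else NA,
        b = if (model == "linear") unname(cf["b"]) else NA,
        n_coef = if (model == "briere") unname(cf["n_coef"]) else NA,
        m = if (model == "briere") unname(cf["m"]) else NA,
        t_b = fit$t_b,
        t_l = if (model == "briere") fit$t_l else NA,
        t_opt = if (model == "briere") unname(fit$t_opt) else NA,
        dd = if (model == "linear") fit$dd else NA,
        r_squared = fit$r.squared,
        n_obs = fit$n_obs)
    }
  }
  summary <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  if (!is.null(summary)) rownames(summary) <- NULL
  structure(list(fits = fits,
                 failures = if (length(failures) > 0)
                   do.call(rbind, failures) else NULL,
                 summary = summary),
            class = "devrate_groups")
}

#' @export
print.devrate_groups <- function(x, digits = 4, ...) {
  cat("Development-rate fits by species and sex\n")
  if (!is.null(x$summary)) {
    s <- x$summary
    num <- vapply(s, is.numeric, logical(1))
    s[num] <- lapply(s[num], signif, digits)
    print(s)
  }
  if (!is.null(x$failures)) {
    cat("\nFailed fits:\n")
    print(x$failures)
  }
  invisible(x)
}

#' Write machine-readable fit reports
#'
#' Writes a JSON report (per species-sex group: both models' parameters,
#' approximate standard errors, derived quantities and diagnostics, at full
#' precision) and a flat CSV summary with one row per group and model.
#'
#' @param groups A `"devrate_groups"` object from [fit_groups()].
#' @param dir Output directory (created if needed).
#' @return Character vector of the paths written, invisibly.
#' @export
write_fit_report <- function(groups, dir) {
  stopifnot(inherits(groups, "devrate_groups"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(dir, "fit_report.json")
  csv_path <- file.path(dir, "fit_summary.csv")
  payload <- lapply(groups$fits, function(by_model) {
    lapply(by_model, function(fit) {
      out <- list(
        model = fit$model,
        coefficients = as.list(fit$coefficients),
        approx_se = as.list(fit$se),
        r_squared = fit$r.squared,
        n_obs = fit$n_obs,
        n_temperatures = fit$n_temps)
      if (fit$model == "linear") {
        out$t_b <- fit$t_b
        out$degree_days <- fit$dd
      } else {
        out$t_b <- fit$t_b
        out$t_l <- fit$t_l
        out$t_opt <- unname(fit$t_opt)
        out$rss <- fit$rss
        out$converged <- fit$convergence
        out$n_starts <- fit$n_starts
        out$at_boundary <- fit$at_boundary
      }
      out
    })
  })
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(groups$summary, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
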