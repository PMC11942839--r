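#' Default species parameters for the life-table simulator
#'
#' Two pupal parasitoid species with sex-specific Briere development
#' parameters, a logistic survival window, and a temperature-independent
#' sex ratio. The development parameters are fitted values reported for
#' *Chouioia cunea* and *Psychophagus omnivorus*; the survival windows and
#' sex ratios are round-number choices that reproduce the qualitative
#' pattern observed in rearing: *C. cunea* emerges from 15 to 30 deg C with
#' a strongly female-biased progeny, *P. omnivorus* only from 20 to 30 deg C
#' with a male-biased progeny.
#'
#' @return Named list of per-species specifications, each with elements
#'   `female` and `male` (lists `n_coef`, `t_b`, `t_l`, `m`), `survival`
#'   (list `p_max`, `t_lo`, `t_hi`, `slope`) and `sex_ratio`
#'   (probability an offspring is female).
#' @export
default_species_params <- function() {
  list(
    "C. cunea" = list(
      female = list(n_coef = 5.74e-5, t_b = 12.57, t_l = 33.0, m = 2.4),
      male   = list(n_coef = 6.0e-5,  t_b = 11.1,  t_l = 33.0, m = 3.0),
      survival = list(p_max = 0.7, t_lo = 13.5, t_hi = 32, slope = 0.8),
      sex_ratio = 0.97
    ),
    "P. omnivorus" = list(
      female = list(n_coef = 1.1e-5, t_b = 11.6, t_l = 36.0, m = 0.9),
      male   = list(n_coef = 1.0e-5, t_b = 10.1, t_l = 36.0, m = 0.92),
      survival = list(p_max = 0.85, t_lo = 18.5, t_hi = 32.5, slope = 0.8),
      sex_ratio = 0.2
    )
  )
}

#' Configuration for the life-table simulator
#'
#' Describes a constant-temperature rearing experiment: a set of species
#' with known (true) Briere development curves, rearing temperatures,
#' individuals per cell, multiplicative lognormal noise on development time,
#' and a seed. The defaults emulate the design of a two-parasitoid rearing
#' study: 2 species x 2 sexes x 5 constant temperatures (10-30 deg C) with
#' 50 individuals per cell.
#'
#' @param species Per-species parameter list as in
#'   [default_species_params()].
#' @param temperatures Constant rearing temperatures, deg C.
#' @param n_per_cell Individuals per rearing cell, >= 1: per species x sex x
#'   temperature under the default fixed design of [simulate_lifetable()],
#'   per species x temperature under its Bernoulli sex-assignment mode.
#' @param noise_sigma Standard deviation of the lognormal multiplicative
#'   noise on development time (dimensionless, >= 0). Noise is placed on
#'   time, not rate, which guarantees positive times and right-skewed
#'   development-time distributions.
#' @param seed Integer seed for the pseudo-random stream; identical
#'   configurations give byte-identical output.
#' @return A validated list of class `"sim_config"`.
#' @seealso [simulate_lifetable()], [recovery_experiment()]
#' @export
sim_config <- function(species = default_species_params(),
                       temperatures = c(10, 15, 20, 25, 30),
                       n_per_cell = 50, noise_sigma = 0.05, seed = 1) {
  stopifnot(is.list(species), length(species) >= 1,
            !is.null(names(species)), all(nzchar(names(species))))
  for (sp in names(species)) {
    s <- species[[sp]]
    for (sx in c("female", "male")) {
      p <- s[[sx]]
      if (is.null(p)) stop("species '", sp, "' lacks '", sx, "' parameters")
      stopifnot(p$n_coef > 0, p$m > 0, p$t_b < p$t_l)
    }
    stopifnot(s$survival$p_max >= 0, s$survival$p_max <= 1,
              s$sex_ratio >= 0, s$sex_ratio <= 1)
  }
  if (length(temperatures) < 1 || any(!is.finite(temperatures)))
    stop("'temperatures' must be finite")
  if (length(n_per_cell) != 1 || n_per_cell < 1 ||
      n_per_cell != round(n_per_cell))
    stop("'n_per_cell' must be an integer >= 1")
  if (noise_sigma < 0) stop("'noise_sigma' must be >= 0")
  seed <- as.integer(seed)
  structure(list(species = species, temperatures = as.numeric(temperatures),
                 n_per_cell = as.integer(n_per_cell),
                 noise_sigma = noise_sigma, seed = seed),
            class = "sim_config")
}

.survival_prob <- function(temp, surv, pars) {
  if (temp <= pars$t_b || temp >= pars$t_l) return(0)
  surv$p_max * stats::plogis((temp - surv$t_lo) / surv$slope) *
    stats::plogis((surv$t_hi - temp) / surv$slope)
}

#' Simulate a constant-temperature life table
#'
#' Draws individual rearing records from known Briere development curves.
#' For each species x temperature cell, `n_per_cell` individuals are
#' assigned a sex (Bernoulli with the species' female ratio), then emerge
#' with probability given by the species' logistic survival window — forced
#' to zero outside the sex's `(t_b, t_l)` developmental window, where
#' development is theoretically impossible. Emerged individuals get
#' \deqn{dev\_time = \frac{1}{D(T)} \exp(\varepsilon), \quad
#'       \varepsilon \sim N(0, \sigma^2)}
#' with \eqn{D(T)} the true Briere rate. The same configuration (including
#' seed) always produces identical records.
#'
#' @param config A [sim_config()] object.
#' @param design `"fixed"` (default): `n_per_cell` individuals of each sex
#'   per species x temperature, the balanced design of a rearing life table
#'   (2 species x 2 sexes x 5 temperatures x 50 = 1000 records with the
#'   defaults). `"bernoulli"`: `n_per_cell` individuals per species x
#'   temperature with sex drawn Bernoulli from the species' female ratio,
#'   for emulating observed progeny sex ratios.
#' @return A `"lifetable"` data frame (one row per individual, emerged or
#'   not), as from [read_lifetable()].
#' @examples
#' lt <- simulate_lifetable(sim_config(seed = 42))
#' table(lt$species, lt$emerged)
#' @export
simulate_lifetable <- function(config, design = c("fixed", "bernoulli")) {
  stopifnot(inherits(config, "sim_config"))
  design <- match.arg(design)
  set.seed(config$seed)
  rows <- list()
  for (sp in names(config$species)) {
    spec <- config$species[[sp]]
    for (temp in config$temperatures) {
      sex <- if (design == "fixed") {
        rep(c("female", "male"), each = config$n_per_cell)
      } else {
        ifelse(stats::runif(config$n_per_cell) < spec$sex_ratio,
               "female", "male")
      }
      n <- length(sex)
      emerged <- logical(n)
      dev_time <- rep(NA_real_, n)
      for (i in seq_len(n)) {
        pars <- spec[[sex[i]]]
        p <- .survival_prob(temp, spec$survival, pars)
        if (p > 0) {
          rate <- briere_rate(temp, pars$n_coef, pars$t_b, pars$t_l, pars$m)
          if (rate <= 0)
            stop("configuration error: P(emerge) > 0 at ", temp,
                 " degC but the true development rate there is 0")
          emerged[i] <- stats::runif(1) < p
          if (emerged[i])
            dev_time[i] <- (1 / rate) *
              exp(stats::rnorm(1, 0, config$noise_sigma))
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        species = sp, sex = sex, temperature = temp,
        dev_time = dev_time, emerged = emerged,
        replicate = rep(1:10, length.out = n),
        aggregated = FALSE, weight = 1,
        stringsAsFactors = FALSE)
    }
  }
  .as_lifetable(do.call(rbind, rows),
                non_developing = NULL, rejected = NULL)
}

#' Parameter-recovery experiment
#'
#' Simulates replicate life tables from known parameters, refits both rate
#' models to each replicate, and summarises how well the estimators recover
#' the truth. Replicate `r` uses `config$seed + r`, so replicates are
#' independent yet reproducible. For the Briere model the errors are
#' measured against the generating parameters; for the linear model only the
#' lower threshold has a truth to compare against (the generating Briere
#' `t_b`), and its error quantifies the well-known extrapolation bias of the
#' linear method. Fit failures are counted, not fatal.
#'
#' @param config A [sim_config()] object (the truth).
#' @param n_replicates Number of simulated datasets, >= 1.
#' @param models Which models to refit.
#' @param sexes Which sex groups to refit (default both).
#' @param n_starts Multistart grid for the Briere refits (see [devrate()]).
#' @return A list of class `"recovery_report"`: `estimates` (one row per
#'   replicate x group x model with the recovered parameters) and `summary`
#'   (bias, RMSE and median absolute error per group, model and parameter),
#'   plus the failure count.
#' @export
recovery_experiment <- function(config, n_replicates,
                                models = c("linear", "briere"),
                                sexes = c("female", "male"),
                                n_starts = c(5, 5, 5)) {
  stopifnot(inherits(config, "sim_config"),
            n_replicates >= 1, n_replicates == round(n_replicates))
  models <- match.arg(models, several.ok = TRUE)
  sexes <- match.arg(sexes, several.ok = TRUE)
  est <- list()
  failures <- 0L
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    lt <- simulate_lifetable(cfg)
    obs_all <- rates_from_records(lt)
    for (sp in names(config$species)) {
      for (sx in sexes) {
        obs <- obs_all[obs_all$species == sp & obs_all$sex == sx, ,
                       drop = FALSE]
        if (nrow(obs) == 0) next  # no individuals of this sex drawn
        truth <- config$species[[sp]][[sx]]
        if ("linear" %in% models) {
          fit <- tryCatch(
            suppressWarnings(devrate(obs, model = "linear")),
            error = function(e) NULL)
          if (is.null(fit)) failures <- failures + 1L else
            est[[length(est) + 1]] <- data.frame(
              replicate = r, species = sp, sex = sx, model = "linear",
              n_coef = NA, t_b = fit$t_b, t_l = NA, m = NA,
              true_t_b = truth$t_b, true_t_l = truth$t_l,
              true_n_coef = truth$n_coef, true_m = truth$m)
        }
        if ("briere" %in% models) {
          fit <- tryCatch(
            suppressWarnings(devrate(obs, model = "briere",
                                     n_starts = n_starts)),
            error = function(e) NULL)
          if (is.null(fit)) failures <- failures + 1L else
            est[[length(est) + 1]] <- data.frame(
              replicate = r, species = sp, sex = sx, model = "briere",
              n_coef = unname(coef(fit)["n_coef"]), t_b = fit$t_b,
              t_l = fit$t_l, m = unname(coef(fit)["m"]),
              true_t_b = truth$t_b, true_t_l = truth$t_l,
              true_n_coef = truth$n_coef, true_m = truth$m)
        }
      }
    }
  }
  estimates <- do.call(rbind, est)
  summary <- .recovery_summary(estimates)
  structure(list(estimates = estimates, summary = summary,
                 failures = failures, n_replicates = n_replicates),
            class = "recovery_report")
}

.recovery_summary <- function(est) {
  if (is.null(est) || nrow(est) == 0) return(NULL)
  pieces <- list()
  specs <- list(n_coef = "true_n_coef", t_b = "true_t_b",
                t_l = "true_t_l", m = "true_m")
  for (grp in split(est, list(est$species, est$sex, est$model), drop = TRUE)) {
    for (par in names(specs)) {
      err <- grp[[par]] - grp[[specs[[par]]]]
      if (all(is.na(err))) next
      pieces[[length(pieces) + 1]] <- data.frame(
        species = grp$species[1], sex = grp$sex[1], model = grp$model[1],
        parameter = par, truth = grp[[specs[[par]]]][1],
        bias = mean(err, na.rm = TRUE),
        rmse = sqrt(mean(err^2, na.rm = TRUE)),
        mae = stats::median(abs(err), na.rm = TRUE))
    }
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  cat(sprintf("Parameter recovery over %d replicate dataset(s); %d fit failure(s)\n",
              x$n_replicates, x$failures))
  if (!is.null(x$summary)) {
    s <- x$summary
    s[c("truth", "bias", "rmse", "mae")] <-
      lapply(s[c("truth", "bias", "rmse", "mae")], signif, digits)
    print(s)
  }
  invisible(x)
}
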