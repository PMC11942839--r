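# Shared fixture builders: everything is generated in code at test time.

# Write a life-table CSV (individual layout) from a vector of row strings.
write_lifetable_csv <- function(rows,
                                header = "species,sex,temperature_C,dev_time_days,emerged,replicate",
                                path = tempfile(fileext = ".csv")) {
  writeLines(c(header, rows), path)
  path
}

write_series_csv <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Noiseless rate observations along a true Briere curve.
briere_obs <- function(temps, n_coef, t_b, t_l, m) {
  data.frame(temperature = temps,
             rate = briere_rate(temps, n_coef, t_b, t_l, m))
}

# Fitted Briere parameters reported for the four species-sex groups
# (C. cunea / P. omnivorus x female / male).
reported_briere_params <- function() {
  list(
    cc_female = list(n_coef = 5.74e-5, t_b = 12.57, t_l = 33.0, m = 2.4),
    cc_male   = list(n_coef = 6e-5,    t_b = 11.1,  t_l = 33.0, m = 3.0),
    po_female = list(n_coef = 1.1e-5,  t_b = 11.6,  t_l = 36.0, m = 0.9),
    po_male   = list(n_coef = 1.0e-5,  t_b = 10.1,  t_l = 36.0, m = 0.92)
  )
}

# Single-species, single-truth simulation config used in recovery tests.
one_group_config <- function(n_per_cell = 50, noise_sigma = 0.05, seed = 1,
                             temperatures = c(10, 15, 20, 25, 30),
                             params = list(n_coef = 5.74e-5, t_b = 12.57,
                                           t_l = 33, m = 2.4)) {
  sim_config(
    species = list(test_sp = list(
      female = params, male = params,
      survival = list(p_max = 0.7, t_lo = 13.5, t_hi = 32, slope = 0.8),
      sex_ratio = 0.5)),
    temperatures = temperatures, n_per_cell = n_per_cell,
    noise_sigma = noise_sigma, seed = seed)
}
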