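test_that("the linear fit reproduces the exact line through two points", {
  obs <- data.frame(temperature = c(20, 30), rate = c(0.02, 0.04))
  fit <- devrate(obs, model = "linear")
  expect_equal(unname(coef(fit)), c(-0.02, 0.002), tolerance = 1e-12)
  expect_equal(fit$t_b, 10, tolerance = 1e-10)
  expect_equal(fit$dd, 500, tolerance = 1e-10)
  expect_equal(fit$r.squared, 1, tolerance = 1e-12)
})

test_that("the linear fit matches closed-form OLS on four mean rates", {
  # mean egg-to-adult times 115, 48.8, 23.13, 21.50 d at 15-30 degC
  temps <- c(15, 20, 25, 30)
  rates <- 1 / c(115, 48.8, 23.13, 21.50)
  # independent closed-form OLS oracle
  b_exp <- sum((temps - mean(temps)) * (rates - mean(rates))) /
    sum((temps - mean(temps))^2)
  a_exp <- mean(rates) - b_exp * mean(temps)
  fit <- devrate(data.frame(temperature = temps, rate = rates),
                 model = "linear")
  expect_equal(unname(coef(fit)["b"]), b_exp, tolerance = 1e-12)
  expect_equal(unname(coef(fit)["a"]), a_exp, tolerance = 1e-12)
  expect_equal(b_exp, 2.724e-3, tolerance = 1e-3)
  expect_equal(a_exp, -3.156e-2, tolerance = 1e-3)
  expect_equal(fit$t_b, 11.59, tolerance = 1e-3)
})

test_that("identical rates give a zero slope and undefined threshold", {
  obs <- data.frame(temperature = c(15, 20, 25), rate = rep(0.02, 3))
  expect_warning(fit <- devrate(obs, model = "linear"), "non-positive slope")
  expect_equal(unname(coef(fit)["b"]), 0, tolerance = 1e-15)
  expect_true(is.na(fit$t_b))
  expect_true(is.na(fit$dd))
  expect_true(is.na(fit$r.squared))
})

test_that("fits fail below two distinct temperatures", {
  obs <- data.frame(temperature = c(25, 25, 25), rate = c(0.04, 0.05, 0.045))
  expect_error(devrate(obs, model = "linear"), "2 distinct temperatures")
})

test_that("threshold and degree-day identities match reported values", {
  expect_equal(round(linear_lower_threshold(-3.52e-2, 2.94e-3), 2), 11.97)
  expect_equal(linear_lower_threshold(0, 0.01), 0)
  expect_error(linear_lower_threshold(1, 0), "undefined")
  expect_equal(round(linear_degree_days(2.94e-3), 1), 340.1)
  expect_equal(round(linear_degree_days(2.76e-3), 1), 362.3)
  expect_equal(linear_degree_days(0.01), 100)
  expect_error(linear_degree_days(-0.001), "non-positive")
  # computed -a/b for the other reported coefficient pairs does not match
  # some published roundings; the identity itself is what is guaranteed
  expect_equal(linear_lower_threshold(-0.0301, 2.76e-3), 10.91, tolerance = 1e-3)
})

test_that("the Briere curve is zero at both thresholds and clamped outside", {
  p <- reported_briere_params()$cc_female
  expect_identical(briere_rate(p$t_b, p$n_coef, p$t_b, p$t_l, p$m), 0)
  expect_identical(briere_rate(p$t_l, p$n_coef, p$t_b, p$t_l, p$m), 0)
  expect_identical(briere_rate(40, p$n_coef, p$t_b, 36, p$m), 0)
  expect_identical(briere_rate(5, p$n_coef, p$t_b, p$t_l, p$m), 0)
  # continuity: approaching either threshold from inside tends to the
  # clamped outside value 0 (near t_l the decay goes like eps^(1/m))
  vals_lo <- briere_rate(p$t_b + 10^-(3:9), p$n_coef, p$t_b, p$t_l, p$m)
  vals_hi <- briere_rate(p$t_l - 10^-(3:9), p$n_coef, p$t_b, p$t_l, p$m)
  expect_true(all(diff(vals_lo) < 0) && vals_lo[7] < 1e-8)
  expect_true(all(diff(vals_hi) < 0) && vals_hi[7] < 1e-3)
  expect_equal(briere_rate(25, 5.74e-5, 12.57, 33.0, 2.4), 0.0424239,
               tolerance = 1e-5)
  expect_error(briere_rate(25, 1e-5, 30, 20, 2), "greater than 't_b'")
  expect_error(briere_rate(25, 1e-5, 10, 30, -1), "positive")
})

test_that("the closed-form optimum matches known cases", {
  expect_equal(briere_optimum(0, 33, 1), 22, tolerance = 1e-12)
  expect_equal(briere_optimum(12.57, 33.0, 2.4), 28.70, tolerance = 1e-3)
  expect_equal(briere_optimum(11.6, 36, 0.9), 25.81, tolerance = 1e-3)
})

test_that("the closed-form optimum equals brute-force grid maximisation", {
  set.seed(11)
  for (i in 1:40) {
    t_b <- runif(1, 0, 25)
    t_l <- t_b + runif(1, 5, 50 - t_b)
    m <- runif(1, 0.3, 5)
    t_opt <- briere_optimum(t_b, t_l, m)
    grid <- seq(t_b, t_l, by = 1e-3)
    vals <- briere_rate(grid, 1e-5, t_b, t_l, m)
    expect_lt(abs(grid[which.max(vals)] - t_opt), 2e-3)
    expect_gt(t_opt, t_b)
    expect_lt(t_opt, t_l)
  }
})

test_that("R-squared follows its defining identity", {
  expect_equal(r_squared(c(0.01, 0.02, 0.03), c(0.01, 0.02, 0.03)), 1)
  obs <- c(0.01, 0.02, 0.03)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(0.012, 0.02, 0.028)), 0.96, tolerance = 1e-12)
  expect_error(r_squared(rep(0.02, 3), c(0.01, 0.02, 0.03)), "identical")
})

test_that("noiseless Briere data are recovered to high relative accuracy", {
  true <- c(n_coef = 5e-5, t_b = 12, t_l = 33, m = 2)
  obs <- briere_obs(13:32, true["n_coef"], true["t_b"], true["t_l"], true["m"])
  fit <- devrate(obs, model = "briere")
  expect_true(all(abs(coef(fit) - true) / true < 1e-4))
  # least-squares optimality: no worse than the generating parameters
  rss_truth <- sum((obs$rate - briere_rate(obs$temperature, true["n_coef"],
                                           true["t_b"], true["t_l"],
                                           true["m"]))^2)
  expect_lte(fit$rss, rss_truth + 1e-14)
  expect_true(fit$convergence)
})

test_that("the multistart objective beats a brute-force parameter grid", {
  set.seed(21)
  obs <- briere_obs(seq(14, 31, by = 1), 5e-5, 12, 33, 2)
  obs$rate <- obs$rate * exp(rnorm(nrow(obs), 0, 0.05))
  fit <- devrate(obs, model = "briere")
  b <- fit$bounds
  grid <- expand.grid(
    t_b = seq(b$t_b[1], b$t_b[2], length.out = 12),
    t_l = seq(b$t_l[1], b$t_l[2], length.out = 12),
    m = seq(b$m[1], b$m[2], length.out = 12))
  rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
    g <- obs$temperature * (obs$temperature - grid$t_b[i]) *
      (grid$t_l[i] - obs$temperature)^(1 / grid$m[i])
    n_hat <- sum(obs$rate * g) / sum(g^2)
    sum((obs$rate - n_hat * g)^2)
  }, numeric(1))
  expect_lte(fit$rss, min(rss_grid) + 1e-14)
})

test_that("three distinct temperatures fit with an underdetermination warning", {
  obs <- briere_obs(c(20, 25, 30), 1.1e-5, 11.6, 36, 0.9)
  expect_warning(fit <- devrate(obs, model = "briere"), "underdetermined")
  expect_s3_class(fit, "devrate_briere")
  obs2 <- briere_obs(c(20, 25), 1.1e-5, 11.6, 36, 0.9)
  expect_error(devrate(obs2, model = "briere"), "3 distinct temperatures")
})

test_that("fitted linear models satisfy a + b * t_b = 0 exactly", {
  set.seed(33)
  for (i in 1:10) {
    temps <- seq(15, 30, by = 5)
    rates <- pmax(0.002 * (temps - runif(1, 5, 12)), 0) +
      abs(rnorm(length(temps), 0, 1e-3))
    fit <- suppressWarnings(
      devrate(data.frame(temperature = temps, rate = rates), model = "linear"))
    if (!is.na(fit$t_b)) {
      cf <- coef(fit)
      expect_lt(abs(cf["a"] + cf["b"] * fit$t_b), 1e-14)
    }
  }
})

test_that("predict, fitted, residuals and simulate are coherent", {
  obs <- briere_obs(13:32, 5e-5, 12, 33, 2)
  fit <- devrate(obs, model = "briere")
  expect_equal(predict(fit), fitted(fit))
  expect_equal(residuals(fit), obs$rate - fitted(fit))
  expect_equal(predict(fit, newdata = data.frame(temperature = 40)), 0)
  expect_equal(predict(fit, 40, type = "time"), Inf)
  expect_equal(predict(fit, 25, type = "time"),
               1 / predict(fit, 25), tolerance = 1e-12)
  sims <- simulate(fit, nsim = 3, seed = 9)
  expect_equal(dim(sims), c(20L, 3L))
  expect_true(all(sims >= 0))
  # formula interface agrees with the data-frame interface
  fit2 <- devrate(rate ~ temperature, data = obs, model = "briere")
  expect_equal(coef(fit2), coef(fit))
})

test_that("Briere search bounds validate and can be overridden", {
  expect_error(briere_bounds(t_b = c(5, 2)), "increasing")
  obs <- briere_obs(13:32, 5e-5, 12, 33, 2)
  fit <- devrate(obs, model = "briere",
                 bounds = briere_bounds(t_b = c(10, 12.9), t_l = c(32.1, 40)))
  expect_equal(unname(coef(fit)["t_b"]), 12, tolerance = 1e-3)
})
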