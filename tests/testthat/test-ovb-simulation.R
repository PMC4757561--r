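test_that("expected bias formula matches the textbook closed form", {
  expect_equal(expected_ovb(1, 0.2, 1), 0.2)
  expect_equal(expected_ovb(0, 0.2, 1), 0)
  expect_equal(expected_ovb(0.5, 0.2, 1), 0.1)
  expect_equal(expected_ovb(0.7, -0.3, 2), 0.7 * -0.3 / 2)
  expect_error(expected_ovb(1, 0.2, 0), "var_x")
  expect_error(expected_ovb(1, 0.2, -1), "var_x")
})

test_that("gamma calibration solves the correlation equation", {
  # closed-form targets
  expect_equal(calibrate_gamma_max(0, 0.2), 0)
  expect_equal(calibrate_gamma_max(0.1, 0.2), 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(calibrate_gamma_max(0.01, 0.2), 0.05, tolerance = 2e-3)
  # independent root-finding oracle on the correlation equation
  for (rho in c(0.01, 0.05, 0.1, 0.15)) {
    g <- calibrate_gamma_max(rho, 0.2)
    root <- uniroot(function(x) 0.2 * x / sqrt(1 + x^2) - rho,
                    c(0, 1e6), tol = 1e-12)$root
    expect_equal(g, root, tolerance = 1e-8)
  }
  expect_error(calibrate_gamma_max(0.2, 0.2), "no solution")
  expect_error(calibrate_gamma_max(0.5, 0.2), "no solution")
  expect_error(calibrate_gamma_max(-0.1, 0.2), "non-negative")
})

test_that("calibrated gamma reproduces the target correlation in simulation", {
  spec <- dgp_spec(gamma_max = calibrate_gamma_max(0.1, 0.2), n_max = 100)
  set.seed(2024)
  s <- draw_ovb_sample(spec, gamma = spec$gamma_max, n = 1e6)
  expect_lt(abs(abs(cor(s$y, s$x)) - 0.1), 0.005)
})

test_that("sample draws honor the data-generating process", {
  spec <- dgp_spec(beta_star = 0, gamma_max = 0, n_max = 100)
  set.seed(1)
  s <- draw_ovb_sample(spec, gamma = 0, n = 500)
  expect_identical(s$y, s$epsilon)   # both coefficients zero: y is pure noise
  expect_length(s$x, 500)

  set.seed(5)
  big <- draw_ovb_sample(spec, gamma = 0.3, n = 1e6)
  expect_lt(abs(cor(big$x, big$z) - 0.2), 0.005)
  expect_equal(big$y, 0.3 * big$z + big$epsilon)

  set.seed(99); a <- draw_ovb_sample(spec, 0.5, 100)
  set.seed(99); b <- draw_ovb_sample(spec, 0.5, 100)
  expect_identical(a, b)

  expect_error(draw_ovb_sample(spec, 0.5, 2), "degenerate")
})

test_that("omitted regression matches an independent OLS oracle", {
  # fixed 6-point fixture, textbook formulas computed in the helper
  x <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  y <- c(1.2, 1.9, 3.4, 3.1, 5.0, 6.2)
  fit <- fit_omitted_regression(list(x = x, y = y))
  oracle <- simple_ols_oracle(x, y)
  expect_equal(fit$coefficient, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$std_error, oracle$se, tolerance = 1e-12)
  expect_equal(fit$t_stat, oracle$t, tolerance = 1e-12)
  expect_equal(fit$p_value, oracle$p, tolerance = 1e-12)
  expect_equal(fit$df_resid, 4)
  # and against lm() on a larger random sample, with and without intercept
  set.seed(3)
  x2 <- rnorm(80); y2 <- 0.3 * x2 + rnorm(80)
  f2 <- fit_omitted_regression(list(x = x2, y = y2))
  l2 <- summary(lm(y2 ~ x2))$coefficients["x2", ]
  expect_equal(f2$coefficient, unname(l2["Estimate"]), tolerance = 1e-12)
  expect_equal(f2$std_error, unname(l2["Std. Error"]), tolerance = 1e-12)
  expect_equal(f2$p_value, unname(l2["Pr(>|t|)"]), tolerance = 1e-12)
  f3 <- fit_omitted_regression(list(x = x2, y = y2), intercept = FALSE)
  l3 <- summary(lm(y2 ~ x2 - 1))$coefficients["x2", ]
  expect_equal(f3$coefficient, unname(l3["Estimate"]), tolerance = 1e-12)
  expect_equal(f3$std_error, unname(l3["Std. Error"]), tolerance = 1e-12)
})

test_that("perfect fits and degenerate inputs are handled", {
  x <- 1:10
  fit <- fit_omitted_regression(list(x = x, y = 2 * x))
  expect_equal(fit$coefficient, 2, tolerance = 1e-12)
  expect_lt(fit$p_value, 1e-12)
  expect_error(fit_omitted_regression(list(x = rep(1, 10), y = rnorm(10))),
               "constant")
})

test_that("Monte Carlo slope means match the expected-bias formula", {
  spec <- dgp_spec(beta_star = 0, gamma_max = 1, n_max = 400)
  for (g in c(0, 0.25, 0.5, 1)) {
    set.seed(1000 + round(100 * g))
    reps <- 1500
    slopes <- vapply(seq_len(reps), function(i) {
      fit_omitted_regression(draw_ovb_sample(spec, g, 400))$coefficient
    }, 0)
    sem <- sd(slopes) / sqrt(reps)
    expect_lt(abs(mean(slopes) - expected_ovb(g, 0.2, 1)), 3 * sem)
  }
})

test_that("the null simulation yields uniform p-values at the nominal rate", {
  sim <- run_ovb_simulation(dgp_spec(gamma_max = 0, n_max = 1000),
                            iterations = 10000, seed = 17)
  share <- mean(sim$p_value < 0.05)
  se <- sqrt(0.05 * 0.95 / 10000)
  expect_lt(abs(share - 0.05), 3 * se)
  expect_gt(ks.test(sim$p_value, "punif")$p.value, 0.001)
})

test_that("simulation runs are deterministic under a fixed seed and grow with n_max", {
  spec <- dgp_spec(rho_max = 0.1, n_max = 200)
  a <- run_ovb_simulation(spec, iterations = 300, seed = 8)
  b <- run_ovb_simulation(spec, iterations = 300, seed = 8)
  expect_identical(as.data.frame(a), as.data.frame(b))

  lo <- run_ovb_simulation(dgp_spec(rho_max = 0.1, n_max = 100),
                           iterations = 10000, seed = 21)
  hi <- run_ovb_simulation(dgp_spec(rho_max = 0.1, n_max = 10000),
                           iterations = 10000, seed = 22)
  expect_gt(mean(hi$p_value < 0.05), mean(lo$p_value < 0.05))
})
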