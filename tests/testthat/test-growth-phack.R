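test_that("model enumeration is exhaustive, canonical and duplicate-free", {
  m <- enumerate_models(15, 6)
  expect_equal(ncol(m), 5005L)
  expect_equal(ncol(m), choose(15, 6))
  expect_equal(ncol(enumerate_models(4, 0)), 1L)
  # brute-force pair oracle
  pairs <- enumerate_models(5, 2)
  brute <- NULL
  for (i in 1:4) for (j in (i + 1):5) brute <- cbind(brute, c(i, j))
  expect_equal(unname(pairs), brute)
  expect_false(anyDuplicated(split(m, col(m))) > 0)
  expect_error(enumerate_models(5, 6), "invalid parameter")
})

test_that("growth-model fits agree with lm to near machine precision", {
  tab <- tiny_growth_table()
  set.seed(33)
  for (i in 1:5) {
    model <- sort(sample(4, 2))
    rows <- sort(sample(nrow(tab), 30))
    fit <- fit_growth_model(tab, model, rows)
    df <- as.data.frame(tab)[rows, ]
    fml <- reformulate(c("m", paste0("z", model)), response = "g")
    l <- summary(lm(fml, data = df))$coefficients["m", ]
    expect_equal(fit$coefficient, unname(l["Estimate"]), tolerance = 1e-10)
    expect_equal(fit$std_error, unname(l["Std. Error"]), tolerance = 1e-10)
    expect_equal(fit$p_value, unname(l["Pr(>|t|)"]), tolerance = 1e-10)
  }
})

test_that("the fast cross-product fitting path equals the QR path", {
  tab <- tiny_growth_table(n = 60)
  set.seed(44)
  rows <- sample(60, 45)
  xp <- phackcurve:::precompute_xp(tab, rows)
  for (model in list(c(1L, 2L), c(2L, 4L), c(1L, 3L, 4L))) {
    fast <- phackcurve:::fast_fit(xp, model)
    slow <- fit_growth_model(tab, model, rows)
    expect_equal(unname(fast[["coefficient"]]), slow$coefficient, tolerance = 1e-10)
    expect_equal(unname(fast[["std_error"]]), slow$std_error, tolerance = 1e-10)
    expect_equal(unname(fast[["p_value"]]), slow$p_value, tolerance = 1e-10)
  }
})

test_that("exact linear truth and row permutations are recovered", {
  tab <- tiny_growth_table(outcome_fun = function(interest, adj) 3 - 2 * interest)
  fit <- fit_growth_model(tab, c(1L, 2L))
  expect_equal(fit$coefficient, -2, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-12)
  # permuting the row subset leaves the fit unchanged
  rows <- sample(nrow(tab), 30)
  tab2 <- tiny_growth_table()
  a <- fit_growth_model(tab2, c(1L, 3L), rows)
  b <- fit_growth_model(tab2, c(1L, 3L), sample(rows))
  expect_equal(a$coefficient, b$coefficient, tolerance = 1e-12)
  expect_equal(a$std_error, b$std_error, tolerance = 1e-12)
})

test_that("rank-deficient designs are reported with the offending column", {
  tab <- tiny_growth_table()
  df <- as.data.frame(tab)
  df$z9 <- df$z1   # exact duplicate regressor
  tab2 <- growth_table(df, "g", "m", c(paste0("z", 1:4), "z9"))
  expect_error(fit_growth_model(tab2, c(1L, 5L)), "collinear")
})

test_that("null-outcome construction zeroes the interest coefficient exactly", {
  tab <- tiny_growth_table(n = 60)
  no <- construct_null_outcome(tab)
  expect_equal(no$new_outcome,
               as.data.frame(tab)$g - no$beta_star_hat * as.data.frame(tab)$m,
               tolerance = 1e-12)
  refit <- construct_null_outcome(no$table)
  expect_lt(abs(refit$beta_star_hat), 1e-10)
  # adjuster coefficients and residuals carry over unchanged
  expect_equal(refit$full_fit$coefficients[-2], no$full_fit$coefficients[-2],
               tolerance = 1e-9)
  expect_equal(refit$full_fit$residuals, no$full_fit$residuals,
               tolerance = 1e-9)
  # idempotence: a second application returns the same outcome
  expect_equal(refit$new_outcome, no$new_outcome, tolerance = 1e-10)
  expect_true(abs(no$correlation_old_new) <= 1)
})

test_that("an orthogonal interest variable leaves the outcome untouched", {
  tab <- orthogonal_interest_table()
  no <- construct_null_outcome(tab)
  expect_lt(abs(no$beta_star_hat), 1e-10)
  expect_equal(no$new_outcome, as.data.frame(tab)$g, tolerance = 1e-10)
  expect_equal(no$correlation_old_new, 1, tolerance = 1e-12)
})

test_that("vibration analysis enumerates the full sample-by-model grid", {
  tab <- tiny_growth_table(n = 60)
  v <- vibration_analysis(tab, n_samples = 2, size_range = c(40, 55),
                          k = 2, seed = 5)
  expect_equal(attr(v, "n_attempted"), 2L * choose(4, 2))
  expect_equal(nrow(v) + nrow(attr(v, "skipped")), attr(v, "n_attempted"))
  expect_equal(sum(attr(v, "shares")), 1)
  expect_equal(v$transformed_p, -log10(v$p_value))
  # determinism
  v2 <- vibration_analysis(tab, n_samples = 2, size_range = c(40, 55),
                           k = 2, seed = 5)
  expect_identical(as.data.frame(v), as.data.frame(v2))
})

test_that("the p-hacking search returns only target-sign significant hits", {
  tab <- generate_growth_table(default_growth_spec("null-effect"), seed = 42)
  nt <- construct_null_outcome(tab)$table
  cfg <- hacking_config(n_hacked = 150, seed = 10)
  h <- phack_search(nt, cfg)
  expect_equal(nrow(h), 150L)
  expect_true(all(h$p_value < 0.05))
  expect_true(all(h$coefficient < 0))
  expect_true(all(h$n >= 50 & h$n <= 99))
  # every visited model is a member of the canonical enumeration
  expect_true(all(h$model_id >= 1 & h$model_id <= choose(15, 6)))
  # determinism
  h2 <- phack_search(nt, cfg)
  expect_identical(as.data.frame(h), as.data.frame(h2))
})

test_that("the full-sample variant always uses all countries", {
  tab <- generate_growth_table(default_growth_spec("null-effect"), seed = 42)
  nt <- construct_null_outcome(tab)$table
  h <- phack_search(nt, hacking_config(n_hacked = 50, full_sample = TRUE,
                                       seed = 2))
  expect_true(all(h$n == nrow(nt)))
  expect_true(all(h$coefficient < 0 & h$p_value < 0.05))
})

test_that("a table with no negative-significant models exhausts the search", {
  tab <- generate_growth_table(default_growth_spec("no-negative-hit"), seed = 1)
  nt <- construct_null_outcome(tab)$table
  cfg <- hacking_config(n_hacked = 5, max_attempts = 5, seed = 3)
  err <- tryCatch(phack_search(nt, cfg), error = identity)
  expect_s3_class(err, "phack_search_exhausted")
  expect_match(conditionMessage(err), "search exhausted")
  expect_true(is.data.frame(err$hits))
  expect_lt(nrow(err$hits), 5)
})
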