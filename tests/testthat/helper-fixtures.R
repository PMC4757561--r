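# Small in-code fixtures shared across test files.

# A tiny deterministic growth table: 40 rows, 4 adjusters, known structure.
tiny_growth_table <- function(n = 40, n_adj = 4, seed = 101,
                              outcome_fun = NULL) {
  set.seed(seed)
  adj <- matrix(rnorm(n * n_adj), n, n_adj,
                dimnames = list(NULL, paste0("z", seq_len(n_adj))))
  interest <- rnorm(n) + 0.4 * adj[, 1]
  outcome <- if (is.null(outcome_fun)) {
    1 + 0.5 * adj[, 1] - 0.3 * adj[, 2] + rnorm(n)
  } else {
    outcome_fun(interest, adj)
  }
  growth_table(data.frame(g = outcome, m = interest, adj),
               outcome = "g", interest = "m",
               adjusters = colnames(adj))
}

# A table whose interest variable is exactly orthogonal (in sample) to the
# outcome and to every adjuster, so the full-model interest coefficient is 0.
orthogonal_interest_table <- function(n = 50, n_adj = 3, seed = 7) {
  set.seed(seed)
  adj <- matrix(rnorm(n * n_adj), n, n_adj,
                dimnames = list(NULL, paste0("z", seq_len(n_adj))))
  outcome <- 2 + adj %*% c(0.5, -0.2, 0.1) + rnorm(n)
  raw <- rnorm(n)
  # residualize on intercept, outcome and adjusters
  interest <- residuals(lm(raw ~ outcome + adj))
  growth_table(data.frame(g = as.numeric(outcome), m = as.numeric(interest), adj),
               outcome = "g", interest = "m",
               adjusters = colnames(adj))
}

# Independent textbook simple-regression oracle (explicit formulas).
simple_ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  slope <- sum((x - xb) * (y - yb)) / sum((x - xb)^2)
  intercept <- yb - slope * xb
  rss <- sum((y - intercept - slope * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - xb)^2))
  t <- slope / se
  list(slope = slope, se = se, t = t,
       p = 2 * pt(-abs(t), df = n - 2))
}
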