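#' Specify a synthetic growth-regression table
#'
#' Defines the statistical structure of a synthetic stand-in for a
#' cross-country growth table: `n_countries` rows; a variable of interest
#' plus `n_adjusters` adjusting variables drawn from a multivariate normal
#' with exchangeable correlation (off-diagonal `rho_adj` among adjusters,
#' `rho_int` between the variable of interest and each adjuster); and an
#' outcome built as
#' `outcome_mean + beta_star * interest + sum(delta_j * adjuster_j) + noise`.
#' With the default `beta_star = 0` the variable of interest has a known
#' exactly-null effect while confounding paths through the correlated
#' adjusters remain, which is precisely the structure specification search
#' exploits.
#'
#' @param n_countries rows to generate (default 99).
#' @param n_adjusters adjusting variables (default 15).
#' @param rho_adj exchangeable correlation among adjusters (default 0.2).
#' @param rho_int correlation between the variable of interest and each
#'   adjuster (default 0.3).
#' @param delta true adjuster coefficients; default: the first 8 nonzero
#'   with magnitudes decaying geometrically from 0.5 (ratio 0.8) and
#'   alternating signs, the rest zero.
#' @param beta_star true coefficient of the variable of interest (default 0).
#' @param noise_sd residual standard deviation (default 1, the scale of
#'   annualized growth-rate percentage points).
#' @param outcome_mean intercept of the outcome equation (default 2).
#' @param correlation optional full `(n_adjusters + 1)` square correlation
#'   matrix (interest first) overriding the exchangeable default, e.g. to
#'   mimic a real table's sample moments.
#' @return an object of class `synthetic_growth_spec`.
#' @export
synthetic_growth_spec <- function(n_countries = 99, n_adjusters = 15,
                                  rho_adj = 0.2, rho_int = 0.3,
                                  delta = NULL, beta_star = 0,
                                  noise_sd = 1, outcome_mean = 2,
                                  correlation = NULL) {
  if (n_countries <= n_adjusters + 2) {
    stop("invalid spec: need n_countries > n_adjusters + 2")
  }
  if (noise_sd <= 0) stop("invalid spec: noise_sd must be positive")
  if (is.null(delta)) {
    delta <- numeric(n_adjusters)
    nz <- seq_len(min(8, n_adjusters))
    delta[nz] <- 0.5 * 0.8^(nz - 1) * (-1)^(nz - 1)
  }
  if (length(delta) != n_adjusters) {
    stop("invalid spec: delta must have one entry per adjuster")
  }
  p <- n_adjusters + 1L
  if (is.null(correlation)) {
    correlation <- matrix(rho_adj, p, p)
    correlation[1, ] <- correlation[, 1] <- rho_int
    diag(correlation) <- 1
  }
  if (!isSymmetric(unname(correlation)) || nrow(correlation) != p) {
    stop("invalid spec: correlation must be a symmetric ", p, " x ", p, " matrix")
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop("invalid spec: correlation matrix is not positive definite")
  }
  structure(
    list(n_countries = as.integer(n_countries),
         n_adjusters = as.integer(n_adjusters),
         rho_adj = rho_adj, rho_int = rho_int, delta = delta,
         beta_star = beta_star, noise_sd = noise_sd,
         outcome_mean = outcome_mean, correlation = correlation),
    class = "synthetic_growth_spec"
  )
}

#' @export
print.synthetic_growth_spec <- function(x, ...) {
  cat(sprintf("Synthetic growth-table spec: %d countries, %d adjusters\n",
              x$n_countries, x$n_adjusters))
  cat(sprintf("  rho_adj = %g, rho_int = %g, beta* = %g, noise_sd = %g\n",
              x$rho_adj, x$rho_int, x$beta_star, x$noise_sd))
  cat("  delta:", paste(signif(x$delta, 3), collapse = " "), "\n")
  invisible(x)
}

#' Generate a synthetic growth table
#'
#' Draws regressors from the spec's multivariate normal (unit marginal
#' variances, via the Cholesky factor of the correlation matrix) and builds
#' the outcome from the spec's linear model plus Gaussian noise. The result
#' is a fully valid [growth_table()] that every downstream operation accepts
#' unchanged. Columns are named `growth` (outcome), `interest`, and
#' `adj01 ... adjNN`.
#'
#' @param spec a [synthetic_growth_spec()].
#' @param seed optional integer seed for reproducibility.
#' @return a [growth_table()].
#' @examples
#' tab <- generate_growth_table(synthetic_growth_spec(), seed = 1)
#' @export
generate_growth_table <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "synthetic_growth_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_countries
  p <- spec$n_adjusters + 1L
  Z <- matrix(stats::rnorm(n * p), n, p) %*% chol(spec$correlation)
  interest <- Z[, 1]
  adjusters <- Z[, -1, drop = FALSE]
  growth <- spec$outcome_mean + spec$beta_star * interest +
    drop(adjusters %*% spec$delta) + stats::rnorm(n, sd = spec$noise_sd)
  adj_names <- sprintf("adj%02d", seq_len(spec$n_adjusters))
  df <- data.frame(growth = growth, interest = interest, adjusters)
  names(df) <- c("growth", "interest", adj_names)
  rownames(df) <- sprintf("C%03d", seq_len(n))
  growth_table(df, outcome = "growth", interest = "interest",
               adjusters = adj_names)
}

#' Frozen default synthetic-table flavors
#'
#' Two ready-made specs for exercising the specification-search pipeline,
#' calibrated once and frozen:
#'
#' * `"null-effect"`: two strong negative confounders (adjusters 1-2,
#'   correlation 0.5 with the variable of interest, coefficients -0.45), one
#'   strong positive confounder (adjuster 3, correlation 0.45, coefficient
#'   0.4), weak background correlation (0.1) and small mixed-sign
#'   coefficients elsewhere. Most 6-of-15 models omit at least one strong
#'   confounder, so generated tables give the p-hacking search a nontrivial
#'   negative-significant hit rate (on the order of 5-60 percent of
#'   (sample, model) fits, varying with the realized table) while all four
#'   sign-by-significance cells are typically populated — a workable
#'   stand-in for the real cross-country table.
#' * `"no-negative-hit"`: all adjuster coefficients positive with positive
#'   interest-adjuster correlation, so every omitted-variable bias on the
#'   variable of interest is positive and negative-significant hits are
#'   vanishingly rare — the guaranteed-failure fixture for [phack_search()].
#'
#' @param flavor `"null-effect"` or `"no-negative-hit"`.
#' @return a [synthetic_growth_spec()].
#' @export
default_growth_spec <- function(flavor = c("null-effect", "no-negative-hit")) {
  flavor <- match.arg(flavor)
  if (flavor == "null-effect") {
    p <- 16
    C <- matrix(0.2, p, p)
    C[1, ] <- C[, 1] <- c(1, 0.5, 0.5, 0.45, rep(0.1, 12))
    diag(C) <- 1
    delta <- numeric(15)
    delta[1:2] <- -0.45
    delta[3] <- 0.4
    delta[4:8] <- 0.2 * 0.8^(0:4) * (-1)^(4:8)
    synthetic_growth_spec(delta = delta, correlation = C)
  } else {
    delta <- numeric(15)
    delta[1:8] <- 0.5 * 0.8^(0:7)
    synthetic_growth_spec(delta = delta)
  }
}

#' Serialize a synthetic spec to a plain list (config block)
#'
#' The returned list round-trips through [spec_from_config()]: rebuilding
#' the spec and generating with the same seed reproduces an identical table.
#'
#' @param x a [synthetic_growth_spec()].
#' @param ... unused.
#' @return a named list of plain vectors (the correlation matrix stored
#'   row-wise only when it differs from the exchangeable default).
#' @export
as.list.synthetic_growth_spec <- function(x, ...) {
  out <- list(n_countries = x$n_countries, n_adjusters = x$n_adjusters,
              rho_adj = x$rho_adj, rho_int = x$rho_int, delta = x$delta,
              beta_star = x$beta_star, noise_sd = x$noise_sd,
              outcome_mean = x$outcome_mean)
  default_cor <- synthetic_growth_spec(
    n_countries = x$n_countries, n_adjusters = x$n_adjusters,
    rho_adj = x$rho_adj, rho_int = x$rho_int, delta = x$delta,
    beta_star = x$beta_star, noise_sd = x$noise_sd,
    outcome_mean = x$outcome_mean)$correlation
  if (!isTRUE(all.equal(unname(x$correlation), unname(default_cor)))) {
    out$correlation <- as.vector(t(x$correlation))
  }
  out
}

#' Rebuild a synthetic spec from a config list
#'
#' @param config a list as produced by [as.list.synthetic_growth_spec()]
#'   (e.g. parsed from YAML or JSON).
#' @return a [synthetic_growth_spec()].
#' @export
spec_from_config <- function(config) {
  if (!is.null(config$correlation)) {
    p <- config$n_adjusters + 1
    config$correlation <- matrix(as.numeric(config$correlation), p, p,
                                 byrow = TRUE)
  }
  args <- config[intersect(names(config),
                           names(formals(synthetic_growth_spec)))]
  if (!is.null(args$delta)) args$delta <- as.numeric(args$delta)
  do.call(synthetic_growth_spec, args)
}
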