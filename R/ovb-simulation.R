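#' Expected omitted-variable bias of a simple-regression slope
#'
#' For the data-generating process \eqn{y = \beta^* x + \gamma z + \epsilon}
#' estimated while omitting \eqn{z}, the expected asymptotic bias of the
#' fitted slope on \eqn{x} is \eqn{\gamma \, \mathrm{Cov}(x,z) / \mathrm{Var}(x)}.
#'
#' @param gamma coefficient of the omitted confounder.
#' @param cov_xz covariance between the regressor of interest and the
#'   confounder.
#' @param var_x variance of the regressor of interest (must be positive).
#' @return the expected bias, a single number.
#' @examples
#' expected_ovb(1, 0.2, 1)   # 0.2
#' @export
expected_ovb <- function(gamma, cov_xz = 0.2, var_x = 1) {
  if (!is.numeric(var_x) || any(var_x <= 0)) {
    stop("var_x must be positive")
  }
  gamma * cov_xz / var_x
}

#' Calibrate the confounder-coefficient bound to a target correlation
#'
#' Under the null data-generating process (\eqn{\beta^* = 0}, unit variances
#' of \eqn{x}, \eqn{z} and \eqn{\epsilon}), the population correlation
#' between outcome and regressor of interest is
#' \deqn{\rho_{yx}(\gamma) = \frac{\gamma\,\mathrm{Cov}(x,z)}{\sqrt{\gamma^2 + 1}}}
#' because \eqn{\mathrm{Var}(y) = \gamma^2 + 1}. Solving
#' \eqn{\rho_{yx}(\gamma) = \rho_{\max}} for \eqn{\gamma} gives the exact root
#' \deqn{\gamma_{\max} = \frac{\rho_{\max}}{\sqrt{\mathrm{Cov}(x,z)^2 - \rho_{\max}^2}}.}
#' The attainable correlation is bounded by \eqn{|\mathrm{Cov}(x,z)|} as
#' \eqn{\gamma \to \infty}, so `rho_max >= |cov_xz|` has no solution.
#'
#' @param rho_max targeted maximum expected correlation between outcome and
#'   regressor of interest (non-negative).
#' @param cov_xz covariance between regressor and confounder.
#' @return the calibrated `gamma_max`, a single non-negative number.
#' @examples
#' calibrate_gamma_max(0.1, 0.2)   # 1 / sqrt(3)
#' @export
calibrate_gamma_max <- function(rho_max, cov_xz = 0.2) {
  if (!is.numeric(rho_max) || length(rho_max) != 1 || rho_max < 0) {
    stop("rho_max must be a single non-negative number")
  }
  if (rho_max == 0) return(0)
  if (rho_max >= abs(cov_xz)) {
    stop("no solution: rho_max must be below |cov_xz| (attainable correlation ",
         "is bounded by |cov_xz| as gamma grows)")
  }
  rho_max / sqrt(cov_xz^2 - rho_max^2)
}

#' Specify the trivariate data-generating process
#'
#' Bundles the parameters of the omitted-variable-bias simulator: the true
#' effect `beta_star` of the regressor of interest, the covariance `cov_xz`
#' between regressor and confounder, the upper bound `gamma_max` of the
#' uniform distribution from which the confounder coefficient is drawn each
#' iteration, and the sample-size range. `gamma_max` may be given directly or
#' calibrated from a target maximum expected correlation `rho_max` via
#' [calibrate_gamma_max()]. Variances of the regressor, confounder and noise
#' are fixed at one.
#'
#' @param beta_star true effect of the regressor of interest (default 0, an
#'   exact null).
#' @param cov_xz covariance between regressor and confounder; `|cov_xz| < 1`.
#' @param gamma_max non-negative upper bound of the confounder coefficient;
#'   exactly one of `gamma_max` and `rho_max` must be supplied.
#' @param rho_max target maximum expected correlation, used to calibrate
#'   `gamma_max` when the latter is not given.
#' @param n_min,n_max inclusive bounds of the discrete-uniform sample-size
#'   distribution.
#' @return an object of class `dgp_spec`.
#' @examples
#' dgp_spec(rho_max = 0.1, n_max = 1000)
#' @export
dgp_spec <- function(beta_star = 0, cov_xz = 0.2, gamma_max = NULL,
                     rho_max = NULL, n_min = 50, n_max = 1000) {
  if (abs(cov_xz) >= 1) stop("invalid parameter: |cov_xz| must be < 1")
  if (is.null(gamma_max) && is.null(rho_max)) {
    stop("supply either gamma_max or rho_max")
  }
  if (!is.null(gamma_max) && !is.null(rho_max)) {
    stop("supply only one of gamma_max and rho_max")
  }
  if (is.null(gamma_max)) gamma_max <- calibrate_gamma_max(rho_max, cov_xz)
  if (gamma_max < 0) stop("invalid parameter: gamma_max must be >= 0")
  n_min <- as.integer(n_min); n_max <- as.integer(n_max)
  if (n_min <= 0 || n_min > n_max) stop("invalid parameter: need 0 < n_min <= n_max")
  structure(
    list(beta_star = beta_star, cov_xz = cov_xz, gamma_max = gamma_max,
         rho_max = rho_max, n_min = n_min, n_max = n_max),
    class = "dgp_spec"
  )
}

#' @export
print.dgp_spec <- function(x, ...) {
  cat("Omitted-variable-bias DGP\n")
  cat(sprintf("  beta* = %g, Cov(x,z) = %g, gamma_max = %.5g%s\n",
              x$beta_star, x$cov_xz, x$gamma_max,
              if (!is.null(x$rho_max))
                sprintf(" (calibrated to rho_max = %g)", x$rho_max) else ""))
  cat(sprintf("  n ~ discrete Uniform[%d, %d]\n", x$n_min, x$n_max))
  invisible(x)
}

#' Draw one sample from the data-generating process
#'
#' Draws `x`, `z`, `epsilon` of length `n` from a multivariate standard
#' normal with `Cov(x, z) = spec$cov_xz` and `epsilon` independent of both
#' (exogeneity by construction), then forms the outcome
#' `y = beta_star * x + gamma * z + epsilon`. Uses the current R random
#' stream; seed it with [set.seed()] for reproducibility.
#'
#' @param spec a [dgp_spec()].
#' @param gamma realized confounder coefficient for this draw.
#' @param n realized sample size (at least 3).
#' @return an object of class `ovb_sample`: a list with vectors `x`, `z`,
#'   `epsilon`, `y` and scalars `gamma`, `n`.
#' @export
draw_ovb_sample <- function(spec, gamma, n) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (n < 3) stop("degenerate sample: need n >= 3")
  if (gamma < 0) stop("gamma must be >= 0")
  x <- stats::rnorm(n)
  # z = r x + sqrt(1 - r^2) w gives unit variance and Cov(x, z) = r
  z <- spec$cov_xz * x + sqrt(1 - spec$cov_xz^2) * stats::rnorm(n)
  epsilon <- stats::rnorm(n)
  structure(
    list(x = x, z = z, epsilon = epsilon,
         y = spec$beta_star * x + gamma * z + epsilon,
         gamma = gamma, n = as.integer(n)),
    class = "ovb_sample"
  )
}

#' Fit the omitted regression of outcome on the regressor of interest alone
#'
#' Regresses `y` on `x` while omitting the confounder `z`, the step that
#' converts confounding into omitted-variable bias. By default an intercept
#' is included (all variables are mean zero, so this is asymptotically
#' immaterial but matches standard finite-sample t-test conventions);
#' `intercept = FALSE` drops it. Inference uses the Student t distribution
#' with the residual degrees of freedom.
#'
#' @param sample an `ovb_sample` from [draw_ovb_sample()], or any list with
#'   numeric `x` and `y` of equal length.
#' @param intercept include an intercept term?
#' @return an `ols_fit` (see [ols_fit()]).
#' @export
fit_omitted_regression <- function(sample, intercept = TRUE) {
  x <- sample$x; y <- sample$y
  n <- length(x)
  if (n < 3 || length(y) != n) stop("degenerate sample: need n >= 3 with equal lengths")
  if (stats::var(x) == 0) stop("collinear design matrix: x is constant")
  # closed-form simple regression; the QR engine is the slow path oracle
  if (intercept) {
    mx <- mean(x); my <- mean(y)
    xc <- x - mx
    sxx <- sum(xc^2)
    slope <- sum(xc * (y - my)) / sxx
    df <- n - 2L
    rss <- sum((y - my - slope * xc)^2)
  } else {
    sxx <- sum(x^2)
    slope <- sum(x * y) / sxx
    df <- n - 1L
    rss <- sum((y - slope * x)^2)
  }
  se <- sqrt(rss / df / sxx)
  new_ols_fit(coefficient = slope, std_error = se, n = n, df_resid = df)
}

#' Run the omitted-variable-bias Monte Carlo experiment
#'
#' Each iteration draws a confounder coefficient `gamma ~ Uniform[0,
#' gamma_max]`, a sample size `n` from a discrete uniform on
#' `[n_min, n_max]`, a fresh sample from the data-generating process (all
#' variables resampled — the conservative design with no re-drawing of
#' `gamma` alone), and fits the omitted regression. The collection of fits
#' is the raw material for a p-curve.
#'
#' @param spec a [dgp_spec()].
#' @param iterations number of Monte Carlo iterations (default 20000; the
#'   full-replication scale is 500000).
#' @param seed optional integer seed; sets the R random stream so that the
#'   run is a pure function of `(spec, iterations, seed)`.
#' @param intercept passed to [fit_omitted_regression()].
#' @param alpha significance threshold recorded for summaries.
#' @return an object of class `ovb_sim`: a data frame with columns
#'   `iteration`, `n`, `gamma`, `coefficient`, `std_error`, `t_stat`,
#'   `p_value`, with the spec and settings in attributes.
#' @examples
#' sim <- run_ovb_simulation(dgp_spec(gamma_max = 0, n_max = 100),
#'                           iterations = 200, seed = 1)
#' summary(sim)
#' @export
run_ovb_simulation <- function(spec, iterations = 20000, seed = NULL,
                               intercept = TRUE, alpha = 0.05) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (iterations < 1) stop("iterations must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  it <- as.integer(iterations)
  n_v <- integer(it); g_v <- numeric(it)
  coef_v <- numeric(it); se_v <- numeric(it); p_v <- numeric(it)
  span <- spec$n_max - spec$n_min + 1L
  for (i in seq_len(it)) {
    g <- stats::runif(1, 0, spec$gamma_max)
    n <- spec$n_min - 1L + sample.int(span, 1L)
    fit <- fit_omitted_regression(draw_ovb_sample(spec, g, n), intercept)
    n_v[i] <- n; g_v[i] <- g
    coef_v[i] <- fit$coefficient; se_v[i] <- fit$std_error
    p_v[i] <- fit$p_value
  }
  out <- data.frame(
    iteration = seq_len(it), n = n_v, gamma = g_v,
    coefficient = coef_v, std_error = se_v, t_stat = coef_v / se_v,
    p_value = p_v
  )
  structure(out, spec = spec, alpha = alpha, seed = seed,
            class = c("ovb_sim", "data.frame"))
}

#' @export
print.ovb_sim <- function(x, ...) {
  spec <- attr(x, "spec"); alpha <- attr(x, "alpha")
  cat(sprintf("Omitted-variable-bias Monte Carlo: %d iterations\n", nrow(x)))
  print(spec)
  cat(sprintf("  share p < %g: %.4f\n", alpha, mean(x$p_value < alpha)))
  invisible(x)
}

#' Summarize a simulation run as a p-curve
#'
#' @param object an `ovb_sim`.
#' @param alpha significance threshold (defaults to the run's).
#' @param n_bins number of p-curve bins.
#' @param ... unused.
#' @return a list with the significant share, the [pcurve()] and its
#'   [skew_summary()].
#' @export
summary.ovb_sim <- function(object, alpha = attr(object, "alpha"),
                            n_bins = 5, ...) {
  pc <- pcurve(object$p_value, alpha = alpha, n_bins = n_bins)
  out <- list(
    iterations = nrow(object),
    share_significant = pc$share_significant,
    pcurve = pc,
    skew = if (pc$n_significant > 0) skew_summary(pc) else NULL
  )
  class(out) <- "summary.ovb_sim"
  out
}

#' @export
print.summary.ovb_sim <- function(x, ...) {
  cat(sprintf("Monte Carlo summary: %d iterations, share significant = %.4f\n",
              x$iterations, x$share_significant))
  print(x$pcurve)
  invisible(x)
}

#' @export
plot.ovb_sim <- function(x, ...) {
  plot(pcurve(x$p_value, alpha = attr(x, "alpha")), ...)
}
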