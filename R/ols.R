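#' Ordinary least squares fit with inference on one coefficient
#'
#' Internal OLS engine shared by the simulation and growth arms. Fits
#' \eqn{y = X b + u} by QR decomposition and returns the point estimate,
#' standard error, t statistic and two-sided p-value (Student t reference
#' with residual degrees of freedom) for a single column of interest.
#'
#' @param X numeric design matrix (including an intercept column if wanted).
#' @param y numeric response vector.
#' @param term column index of the coefficient of interest.
#' @param model_id opaque identifier carried through to the result.
#' @return an object of class `ols_fit`: a list with elements `coefficient`,
#'   `std_error`, `t_stat`, `p_value`, `n`, `df_resid`, `model_id`,
#'   `coefficients` (the full estimate vector) and `residuals`.
#' @keywords internal
ols_fit <- function(X, y, term = 2L, model_id = NA_character_) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("design matrix and response have different lengths")
  if (n <= p) stop("degenerate sample: need more rows than coefficients")
  qx <- qr(X)
  if (qx$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qx$pivot[seq_len(qx$rank)])]
    stop("collinear design matrix; offending columns: ",
         paste(if (length(bad)) bad else "unnamed", collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  df <- n - p
  sigma2 <- sum(res^2) / df
  # (X'X)^{-1} from the R factor of the QR decomposition
  Rinv <- backsolve(qr.R(qx), diag(p))
  xtx_inv <- tcrossprod(Rinv)
  # undo pivoting
  piv <- qx$pivot
  xtx_inv[piv, piv] <- xtx_inv
  se <- sqrt(sigma2 * diag(xtx_inv))
  tv <- beta / se
  new_ols_fit(
    coefficient = unname(beta[term]),
    std_error = unname(se[term]),
    n = n, df_resid = df, model_id = model_id,
    coefficients = beta, residuals = res
  )
}

new_ols_fit <- function(coefficient, std_error, n, df_resid,
                        model_id = NA_character_,
                        coefficients = NULL, residuals = NULL) {
  t_stat <- coefficient / std_error
  structure(
    list(
      coefficient = coefficient,
      std_error = std_error,
      t_stat = t_stat,
      p_value = 2 * stats::pt(-abs(t_stat), df = df_resid),
      n = n,
      df_resid = df_resid,
      model_id = model_id,
      coefficients = coefficients,
      residuals = residuals
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("OLS fit (coefficient of interest)\n")
  cat(sprintf("  estimate: %.6g  SE: %.6g  t: %.4g  p: %.4g  (n = %d, df = %d)\n",
              x$coefficient, x$std_error, x$t_stat, x$p_value, x$n, x$df_resid))
  if (!is.na(x$model_id)) cat("  model:", x$model_id, "\n")
  invisible(x)
}
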