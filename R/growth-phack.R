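#' Construct an exactly-null outcome from a fitted full model
#'
#' Fits the full regression of the outcome on the variable of interest and
#' all adjusters (with intercept), then rebuilds the outcome with the
#' interest coefficient forced to zero:
#' `new_outcome = outcome - beta_hat * interest`. The rebuilt outcome keeps
#' the fitted contribution of every adjuster and the original residuals, so
#' the data's structure is preserved while the true effect of the variable
#' of interest is exactly zero — the ground-truth-null construction on which
#' the specification-search illustration rests.
#'
#' @param table a [growth_table()].
#' @return an object of class `null_outcome`: a list with `new_outcome`,
#'   `full_fit` (the full-model `ols_fit`), `correlation_old_new`,
#'   `beta_star_hat`, `beta_star_p`, and `table` (a [growth_table()] whose
#'   outcome column is replaced by `new_outcome`, ready for downstream use).
#' @export
construct_null_outcome <- function(table) {
  stopifnot(inherits(table, "growth_table"))
  y <- table[[attr(table, "outcome")]]
  X <- full_design(table)
  fit <- ols_fit(X, y, term = 2L, model_id = "full")
  new_y <- y - fit$coefficient * table[[attr(table, "interest")]]
  new_table <- table
  new_table[[attr(table, "outcome")]] <- new_y
  structure(
    list(
      new_outcome = new_y,
      full_fit = fit,
      correlation_old_new = stats::cor(y, new_y),
      beta_star_hat = fit$coefficient,
      beta_star_p = fit$p_value,
      table = new_table
    ),
    class = "null_outcome"
  )
}

#' @export
print.null_outcome <- function(x, ...) {
  cat("Null-outcome construction\n")
  cat(sprintf("  original interest coefficient: %.5g (p = %.3g)\n",
              x$beta_star_hat, x$beta_star_p))
  cat(sprintf("  correlation(old, new outcome): %.4f\n", x$correlation_old_new))
  invisible(x)
}

# intercept + interest + all adjusters, in table column order
full_design <- function(table, rows = NULL) {
  cols <- c(attr(table, "interest"), attr(table, "adjusters"))
  X <- cbind(`(Intercept)` = 1, as.matrix(as.data.frame(table)[, cols]))
  if (!is.null(rows)) X <- X[rows, , drop = FALSE]
  X
}

#' Enumerate all adjuster subsets of a given size
#'
#' Lists every way of choosing `k` of `n_adjusters` adjusting variables, in
#' lexicographic (canonical) order. Each model additionally contains the
#' variable of interest and an intercept by construction. Choosing 6 of 15
#' adjusters yields 5005 models.
#'
#' @param n_adjusters number of available adjusting variables.
#' @param k subset size.
#' @return an integer matrix with `k` rows and `choose(n_adjusters, k)`
#'   columns; column `j` holds the adjuster indices of model `j`.
#' @examples
#' ncol(enumerate_models(15, 6))  # 5005
#' @export
enumerate_models <- function(n_adjusters = 15, k = 6) {
  if (k > n_adjusters || k < 0) {
    stop("invalid parameter: need 0 <= k <= n_adjusters")
  }
  if (k == 0) return(matrix(integer(0), nrow = 0, ncol = 1))
  m <- utils::combn(n_adjusters, k)
  storage.mode(m) <- "integer"
  m
}

#' Fit one growth-regression specification
#'
#' OLS of the (null-constructed or raw) outcome on an intercept, the
#' variable of interest and the model's adjuster subset, on an optional row
#' subset. The returned coefficient and p-value refer to the variable of
#' interest only.
#'
#' @param table a [growth_table()].
#' @param model adjuster selection: an integer vector of indices into
#'   `attr(table, "adjusters")` or a character vector of adjuster names.
#' @param rows optional row indices (a country sample); default all rows.
#' @return an `ols_fit` whose `model_id` records the adjuster indices.
#' @export
fit_growth_model <- function(table, model, rows = NULL) {
  stopifnot(inherits(table, "growth_table"))
  adj <- attr(table, "adjusters")
  if (is.character(model)) model <- match(vapply(model, match_column, "",
                                                 choices = adj), adj)
  model <- as.integer(model)
  if (anyNA(model) || any(model < 1 | model > length(adj)) ||
      anyDuplicated(model)) {
    stop("invalid model: adjuster indices must be distinct and in range")
  }
  if (is.null(rows)) rows <- seq_len(nrow(table))
  if (length(rows) <= length(model) + 2) {
    stop("degenerate sample: row subset too small for the model size")
  }
  X <- full_design(table, rows)[, c(1L, 2L, 2L + model), drop = FALSE]
  y <- table[[attr(table, "outcome")]][rows]
  ols_fit(X, y, term = 2L,
          model_id = paste(sort(model), collapse = "+"))
}

# Fast normal-equations machinery for exhaustive / repeated fitting.
# For a fixed row sample, the cross-products of the FULL design are computed
# once; any sub-model's normal equations are then sub-matrices. Returns the
# interest-coefficient inference for one model, or NULL when the sub-design
# is numerically rank deficient (Cholesky failure).
precompute_xp <- function(table, rows) {
  X <- full_design(table, rows)
  y <- table[[attr(table, "outcome")]][rows]
  list(G = crossprod(X), h = drop(crossprod(X, y)), yty = sum(y * y),
       n = length(rows))
}

fast_fit <- function(xp, model) {
  cols <- c(1L, 2L, 2L + model)
  A <- xp$G[cols, cols]
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(NULL)
  Ainv <- chol2inv(R)
  beta <- drop(Ainv %*% xp$h[cols])
  rss <- max(xp$yty - sum(xp$h[cols] * beta), 0)
  df <- xp$n - length(cols)
  se <- sqrt(rss / df * Ainv[2L, 2L])
  tv <- beta[2L] / se
  c(coefficient = beta[2L], std_error = se,
    p_value = 2 * stats::pt(-abs(tv), df = df))
}

#' Vibration-of-effects analysis over samples and model specifications
#'
#' Draws `n_samples` random country samples (without replacement, sizes from
#' a discrete uniform over `size_range`) and fits every `k`-of-adjusters
#' model on each, mapping out how the interest-variable estimate vibrates
#' across the joint sampling and modelling space. Each estimate is
#' classified into the four sign-by-significance cells at `alpha`.
#' Numerically rank-deficient (sample, model) pairs are skipped and logged.
#'
#' @param table a [growth_table()] (typically the null-outcome table).
#' @param n_samples number of country samples (default 100).
#' @param size_range inclusive sample-size bounds (default `c(50, 99)`).
#' @param k adjusters per model (default 6).
#' @param alpha significance threshold.
#' @param seed optional integer seed.
#' @return an object of class `vibration`: a data frame with columns
#'   `sample_id`, `model_id`, `n`, `coefficient`, `p_value`,
#'   `transformed_p` (`-log10(p)`), with attributes `shares` (the four
#'   sign-by-significance fractions), `quantiles` (1/50/99 percent of both
#'   axes), `n_models`, `n_attempted` and `skipped`.
#' @export
vibration_analysis <- function(table, n_samples = 100, size_range = c(50, 99),
                               k = 6, alpha = 0.05, seed = NULL) {
  stopifnot(inherits(table, "growth_table"))
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(table)
  if (size_range[2] > nr || size_range[1] < 1 || size_range[1] > size_range[2]) {
    stop("size_range must lie within the table's row count")
  }
  if (n_samples < 1) stop("n_samples must be >= 1")
  n_samples <- as.integer(n_samples)
  models <- enumerate_models(length(attr(table, "adjusters")), k)
  M <- ncol(models)
  total <- n_samples * M
  sample_id <- rep(seq_len(n_samples), each = M)
  model_id <- rep(seq_len(M), times = n_samples)
  n_v <- integer(total); coef_v <- numeric(total); p_v <- numeric(total)
  ok <- logical(total)
  span <- size_range[2] - size_range[1] + 1L
  idx <- 0L
  for (s in seq_len(n_samples)) {
    n_s <- size_range[1] - 1L + sample.int(span, 1L)
    rows <- sample.int(nr, n_s)
    xp <- precompute_xp(table, rows)
    for (m in seq_len(M)) {
      idx <- idx + 1L
      f <- fast_fit(xp, models[, m])
      n_v[idx] <- n_s
      if (is.null(f)) next
      ok[idx] <- TRUE
      coef_v[idx] <- f[["coefficient"]]
      p_v[idx] <- f[["p_value"]]
    }
  }
  out <- data.frame(
    sample_id = sample_id[ok], model_id = model_id[ok], n = n_v[ok],
    coefficient = coef_v[ok], p_value = p_v[ok],
    transformed_p = -log10(p_v[ok])
  )
  sig <- out$p_value < alpha
  neg <- out$coefficient < 0
  shares <- c(
    negative_significant = mean(neg & sig),
    negative_insignificant = mean(neg & !sig),
    positive_significant = mean(!neg & sig),
    positive_insignificant = mean(!neg & !sig)
  )
  qs <- c(0.01, 0.5, 0.99)
  structure(out,
            shares = shares,
            quantiles = list(coefficient = stats::quantile(out$coefficient, qs),
                             transformed_p = stats::quantile(out$transformed_p, qs)),
            n_models = M, n_samples = n_samples, n_attempted = total,
            skipped = data.frame(sample_id = sample_id[!ok],
                                 model_id = model_id[!ok]),
            alpha = alpha, seed = seed,
            class = c("vibration", "data.frame"))
}

#' @export
print.vibration <- function(x, ...) {
  cat(sprintf("Vibration analysis: %d samples x %d models = %d fits (%d skipped)\n",
              attr(x, "n_samples"), attr(x, "n_models"),
              attr(x, "n_attempted"), nrow(attr(x, "skipped"))))
  sh <- attr(x, "shares")
  cat(sprintf("  sign x significance shares at alpha = %g:\n", attr(x, "alpha")))
  for (nm in names(sh)) cat(sprintf("    %-24s %6.3f%%\n", nm, 100 * sh[[nm]]))
  invisible(x)
}

#' @export
plot.vibration <- function(x, ...) {
  graphics::plot(x$coefficient, x$transformed_p,
                 pch = ".", xlab = "interest-variable estimate",
                 ylab = "-log10(p)", ...)
  graphics::abline(h = -log10(attr(x, "alpha")))
  q <- attr(x, "quantiles")
  graphics::abline(v = q$coefficient, lty = 2)
  graphics::abline(h = q$transformed_p, lty = 2)
  invisible(x)
}

#' Configuration of the sequential p-hacking search
#'
#' @param alpha significance threshold (default 0.05).
#' @param target_sign sign of the estimates to harvest: `-1` (detrimental
#'   effect, the default) or `+1`.
#' @param n_hacked number of significant estimates to harvest (the
#'   full-scale illustration uses 100000; choose smaller for desk scale).
#' @param sample_size_range inclusive country-sample-size bounds, default
#'   `c(50, 99)`.
#' @param k adjusters per model (default 6).
#' @param full_sample when `TRUE`, every attempt uses all countries and only
#'   the random model-browsing order varies.
#' @param max_attempts safety bound on country samples drawn (default
#'   `100 * n_hacked`).
#' @param seed optional integer seed.
#' @return an object of class `hacking_config`.
#' @export
hacking_config <- function(alpha = 0.05, target_sign = -1, n_hacked = 100000,
                           sample_size_range = c(50, 99), k = 6,
                           full_sample = FALSE, max_attempts = 100 * n_hacked,
                           seed = NULL) {
  if (n_hacked < 1) stop("n_hacked must be >= 1")
  if (max_attempts < n_hacked) stop("max_attempts must be >= n_hacked")
  if (!target_sign %in% c(-1, 1)) stop("target_sign must be -1 or +1")
  structure(
    list(alpha = alpha, target_sign = target_sign, n_hacked = n_hacked,
         sample_size_range = sample_size_range, k = k,
         full_sample = full_sample, max_attempts = max_attempts, seed = seed),
    class = "hacking_config"
  )
}

#' Sequential specification search for significant estimates
#'
#' Emulates p-hacking by specification search: draw a random country sample,
#' browse the enumerated models in a uniformly random order without
#' replacement, keep the FIRST estimate of the interest variable that is
#' significant with the target sign, then draw a fresh sample and repeat;
#' samples yielding no hit contribute nothing. Harvesting stops once
#' `n_hacked` estimates are collected. With `full_sample = TRUE` every
#' attempt uses all countries, so only the browsing order varies.
#'
#' @param table a [growth_table()] (typically the null-outcome table).
#' @param config a [hacking_config()].
#' @return an object of class `phack_set`: a data frame with columns
#'   `hit_index`, `sample_id` (the attempt number), `model_id` (canonical
#'   model index), `n`, `coefficient`, `p_value`, with the config and the
#'   number of attempts in attributes. If `max_attempts` is exhausted first,
#'   an error of class `phack_search_exhausted` is signalled whose `hits`
#'   field carries the estimates found so far.
#' @export
phack_search <- function(table, config) {
  stopifnot(inherits(table, "growth_table"), inherits(config, "hacking_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  nr <- nrow(table)
  rng <- config$sample_size_range
  if (!config$full_sample &&
      (rng[2] > nr || rng[1] < 1 || rng[1] > rng[2])) {
    stop("sample_size_range must lie within the table's row count")
  }
  models <- enumerate_models(length(attr(table, "adjusters")), config$k)
  M <- ncol(models)
  span <- rng[2] - rng[1] + 1L
  nh <- config$n_hacked
  hit_sample <- integer(nh); hit_model <- integer(nh)
  hit_n <- integer(nh); hit_coef <- numeric(nh); hit_p <- numeric(nh)
  hits <- 0L
  attempts <- 0L
  full_xp <- if (config$full_sample) precompute_xp(table, seq_len(nr)) else NULL
  while (hits < nh) {
    if (attempts >= config$max_attempts) {
      found <- seq_len(hits)
      cond <- structure(
        class = c("phack_search_exhausted", "error", "condition"),
        list(message = sprintf(
               "search exhausted: %d attempts yielded %d of %d hits",
               attempts, hits, nh),
             call = sys.call(-1),
             hits = data.frame(hit_index = found,
                               sample_id = hit_sample[found],
                               model_id = hit_model[found],
                               n = hit_n[found],
                               coefficient = hit_coef[found],
                               p_value = hit_p[found])))
      stop(cond)
    }
    attempts <- attempts + 1L
    if (config$full_sample) {
      n_s <- nr
      xp <- full_xp
    } else {
      n_s <- rng[1] - 1L + sample.int(span, 1L)
      xp <- precompute_xp(table, sample.int(nr, n_s))
    }
    for (m in sample.int(M)) {
      f <- fast_fit(xp, models[, m])
      if (is.null(f)) next  # rank-deficient: treat as a non-hit, keep browsing
      if (f[["p_value"]] < config$alpha &&
          sign(f[["coefficient"]]) == config$target_sign) {
        hits <- hits + 1L
        hit_sample[hits] <- attempts
        hit_model[hits] <- m
        hit_n[hits] <- n_s
        hit_coef[hits] <- f[["coefficient"]]
        hit_p[hits] <- f[["p_value"]]
        break
      }
    }
  }
  structure(
    data.frame(hit_index = seq_len(nh), sample_id = hit_sample,
               model_id = hit_model, n = hit_n,
               coefficient = hit_coef, p_value = hit_p),
    config = config, attempts = attempts,
    class = c("phack_set", "data.frame")
  )
}

#' @export
print.phack_set <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("p-hacking search: %d significant %s estimates from %d country samples\n",
              nrow(x), if (cfg$target_sign < 0) "negative" else "positive",
              attr(x, "attempts")))
  cat(sprintf("  median harvested p: %.4g, median estimate: %.4g\n",
              stats::median(x$p_value), stats::median(x$coefficient)))
  invisible(x)
}

#' @export
summary.phack_set <- function(object, n_bins = 5, ...) {
  cfg <- attr(object, "config")
  pc <- pcurve(object$p_value, alpha = cfg$alpha, n_bins = n_bins)
  # all harvested p are significant by construction, so renormalize over hits
  list(pcurve = pc, skew = skew_summary(pc),
       attempts = attr(object, "attempts"),
       hit_rate = nrow(object) / attr(object, "attempts"))
}

#' @export
plot.phack_set <- function(x, n_bins = 5, ...) {
  cfg <- attr(x, "config")
  plot(pcurve(x$p_value, alpha = cfg$alpha, n_bins = n_bins), ...)
}
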