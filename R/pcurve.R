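#' Build a p-curve from a collection of p-values
#'
#' The p-curve is the distribution of statistically significant p-values:
#' values below `alpha` binned into `n_bins` left-open, right-closed
#' intervals partitioning `(0, alpha]`, each bin reported as its share of
#' the significant mass. Values at or above `alpha` are excluded from
#' binning (significance is strict, `p < alpha`) but counted in `n_total`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha significance threshold in `(0, 1)`; default 0.05.
#' @param n_bins number of equal-width bins over `(0, alpha]`; default 5
#'   (bins of width 0.01 at the default threshold).
#' @return an object of class `pcurve`: a list with `bin_edges` (length
#'   `n_bins + 1`), `bin_counts`, `bin_shares`, `n_significant`, `n_total`,
#'   `share_significant` and `alpha`.
#' @examples
#' pcurve(c(0.005, 0.015, 0.045, 0.5))
#' @export
pcurve <- function(p_values, alpha = 0.05, n_bins = 5) {
  p_values <- as.numeric(p_values)
  if (length(p_values) == 0) stop("empty input: no p-values supplied")
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    stop("invalid value: p-values must lie in [0, 1] with no missing values")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (n_bins < 2) stop("need at least 2 bins")
  edges <- seq(0, alpha, length.out = n_bins + 1)
  sig <- p_values[p_values < alpha]
  counts <- if (length(sig)) {
    tabulate(findInterval(sig, edges, left.open = TRUE, all.inside = TRUE),
             nbins = n_bins)
  } else {
    integer(n_bins)
  }
  structure(
    list(
      bin_edges = edges,
      bin_counts = counts,
      bin_shares = if (length(sig)) counts / length(sig) else rep(NA_real_, n_bins),
      n_significant = length(sig),
      n_total = length(p_values),
      share_significant = length(sig) / length(p_values),
      alpha = alpha
    ),
    class = "pcurve"
  )
}

#' Descriptive skew classification of a p-curve
#'
#' Operationalizes the verbal right-skewed / left-skewed / flat reading of a
#' p-curve: `right` when the first bin's share exceeds the last bin's by more
#' than `margin`, `left` for the reverse, `flat` otherwise.
#' `monotone_decreasing` is `TRUE` when the bin shares are non-increasing
#' from left to right. This is a descriptive summary, not an inferential
#' skew test.
#'
#' @param curve a [pcurve()] with at least 2 bins and at least one
#'   significant p-value.
#' @param margin minimum first-minus-last share difference to call a
#'   direction; default 0 (any strict difference).
#' @return a list with `direction` (`"right"`, `"left"` or `"flat"`),
#'   `first_bin_share`, `last_bin_share` and `monotone_decreasing`.
#' @export
skew_summary <- function(curve, margin = 0) {
  stopifnot(inherits(curve, "pcurve"))
  if (curve$n_significant == 0) {
    stop("undefined skew: the p-curve has no significant p-values")
  }
  s <- curve$bin_shares
  first <- s[1]; last <- s[length(s)]
  direction <- if (first - last > margin) "right"
               else if (last - first > margin) "left"
               else "flat"
  list(
    direction = direction,
    first_bin_share = first,
    last_bin_share = last,
    monotone_decreasing = all(diff(s) <= 0)
  )
}

#' @export
print.pcurve <- function(x, digits = 4, ...) {
  cat(sprintf("p-curve: %d of %d p-values significant at p < %g (share %.4f)\n",
              x$n_significant, x$n_total, x$alpha, x$share_significant))
  df <- as.data.frame(x)
  df$share <- round(df$share, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.pcurve <- function(x, ...) {
  nb <- length(x$bin_counts)
  data.frame(
    bin_low = x$bin_edges[seq_len(nb)],
    bin_high = x$bin_edges[-1],
    count = x$bin_counts,
    share = x$bin_shares
  )
}

#' Plot a p-curve as a bar chart
#'
#' Bars show each bin's share of the significant mass; the dashed horizontal
#' line at `1 / n_bins` is the hypothetical uniform distribution expected
#' under an unbiased exact null.
#'
#' @param x a [pcurve()].
#' @param ... passed to [graphics::barplot()].
#' @export
plot.pcurve <- function(x, ...) {
  nb <- length(x$bin_counts)
  labs <- sprintf("(%.3g,%.3g]", x$bin_edges[seq_len(nb)], x$bin_edges[-1])
  graphics::barplot(x$bin_shares, names.arg = labs,
                    ylab = "share of significant p-values",
                    xlab = "p-value bin", ...)
  graphics::abline(h = 1 / nb, lty = 2)
  invisible(x)
}

#' Write p-curve bins to CSV
#'
#' Emits one row per bin with columns `bin_low`, `bin_high`, `count`,
#' `share`, plus a `uniform_reference` column equal to `1 / n_bins` (the
#' dashed-line level of the bar chart).
#'
#' @param curve a [pcurve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pcurve_csv <- function(curve, path) {
  df <- as.data.frame(curve)
  df$uniform_reference <- 1 / nrow(df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read p-values from a one-column CSV
#'
#' @param path CSV file whose first column holds p-values.
#' @return numeric vector of p-values.
#' @export
read_pvalues_csv <- function(path) {
  df <- utils::read.csv(path)
  as.numeric(df[[1]])
}
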