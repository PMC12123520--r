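# Group summaries and two-sample tests for recovery percentages.
#
# Reporting convention: group medians are TRUNCATED (floored), not rounded,
# to two decimals. On the bundled study counts truncation is the convention
# that reproduces the published medians (e.g. 3.43, 9.58, 42.67, 1.11 where
# rounding would give 3.44, 9.59, 42.68, 1.11).

#' Recovery percentages of a set of comparison records
#'
#' @param records Comparison-record data frame (see
#'   \code{\link{comparison_records}}).
#' @param condition Optional condition label to filter on.
#' @param sex_filter Optional sex (\code{"male"}/\code{"female"}) to filter
#'   on.
#' @return Numeric vector \code{100 * detected / expected} at full
#'   precision, in the (stable) order of the filtered records, named by
#'   sample ID.
#' @export
recovery_percentages <- function(records, condition = NULL,
                                 sex_filter = NULL) {
  keep <- rep(TRUE, nrow(records))
  if (!is.null(condition)) keep <- keep & records$condition == condition
  if (!is.null(sex_filter)) keep <- keep & records$sex == sex_filter
  rec <- records[keep, , drop = FALSE]
  if (!nrow(rec)) stop("no records left after filtering")
  if (any(rec$expected <= 0)) stop("recovery undefined where expected = 0")
  out <- 100 * rec$detected / rec$expected
  names(out) <- rec$sample_id
  out
}

#' Median truncated to two decimals
#'
#' The median (middle order statistic, or mean of the two central order
#' statistics for even n) floored to two decimal places — the convention
#' used for all reported group medians. A half-ulp guard absorbs binary
#' floating-point noise so that values landing exactly on a hundredth are
#' not spuriously floored down.
#'
#' @param values Non-empty numeric vector.
#' @return The truncated median.
#' @export
truncated_median <- function(values) {
  if (!length(values)) stop("empty input")
  trunc2(stats::median(values))
}

trunc2 <- function(x) floor(round(x * 100, 9)) / 100

#' Two-sample Student's t test
#'
#' Thin wrapper around \code{\link[stats]{t.test}} exposing the three
#' variants relevant to a two-condition study: \code{pooled}
#' (equal-variance Student statistic, df = n_a + n_b - 2), \code{welch}
#' (unequal variances, Welch–Satterthwaite df) and \code{paired}
#' (one-sample t on within-subject differences). Two-sided p throughout.
#'
#' @param a,b Numeric vectors, each of length >= 2 (equal lengths for the
#'   paired variant).
#' @param variant \code{"pooled"}, \code{"welch"} or \code{"paired"}.
#' @return List of class \code{str_test_result}: \code{statistic},
#'   \code{df}, \code{p_value}, \code{variant}.
#' @export
student_t_test <- function(a, b, variant = c("pooled", "welch", "paired")) {
  variant <- match.arg(variant)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (variant == "paired" && length(a) != length(b))
    stop("paired variant needs equal-length groups")
  fit <- switch(variant,
    pooled = stats::t.test(a, b, var.equal = TRUE),
    welch = stats::t.test(a, b),
    paired = stats::t.test(a, b, paired = TRUE)
  )
  structure(list(statistic = unname(fit$statistic),
                 df = unname(fit$parameter),
                 p_value = unname(fit$p.value),
                 variant = variant),
            class = "str_test_result")
}

#' Kolmogorov–Smirnov normality check
#'
#' One-sample KS test of the values against a normal distribution with the
#' sample's own mean and standard deviation, with the asymptotic p-value
#' from the Kolmogorov distribution. Because the reference parameters are
#' estimated from the same data (the Lilliefors situation), this p-value is
#' anti-conservative: it overstates evidence for normality. It is provided
#' as the conventional screening step for small two-condition studies and
#' is labelled accordingly in reports.
#'
#' @param values Numeric vector, n >= 4, non-degenerate.
#' @return \code{str_test_result} with \code{df = NA} and
#'   \code{variant = "ks_normal"}.
#' @export
ks_normality <- function(values) {
  if (length(values) < 4) stop("need n >= 4")
  s <- stats::sd(values)
  if (!is.finite(s) || s == 0) stop("degenerate input: zero variance")
  fit <- suppressWarnings(
    stats::ks.test(values, "pnorm", mean(values), s, exact = FALSE))
  structure(list(statistic = unname(fit$statistic), df = NA_real_,
                 p_value = unname(fit$p.value), variant = "ks_normal"),
            class = "str_test_result")
}

#' @export
print.str_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, df = %s, p = %.6g\n", x$variant,
              x$statistic, ifelse(is.na(x$df), "-", format(x$df)),
              x$p_value))
  invisible(x)
}

#' Box-plot five-number summary
#'
#' Quartiles by linear interpolation of order statistics (position
#' p (n - 1) + 1, i.e. \code{\link[stats]{quantile}} type 7); whiskers at
#' the most extreme observations within 1.5 IQR of the quartiles.
#'
#' @param values Non-empty numeric vector.
#' @return Named list: \code{q1}, \code{median}, \code{q3},
#'   \code{whisker_low}, \code{whisker_high}.
#' @export
boxplot_stats <- function(values) {
  if (!length(values)) stop("empty input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_low = min(values[values >= q[1] - 1.5 * iqr]),
       whisker_high = max(values[values <= q[3] + 1.5 * iqr]))
}

#' Summarise a group of recovery percentages
#'
#' @param values Numeric vector of percentages.
#' @param group_label Label such as \code{"HSWW"} or \code{"HSWAF"}.
#' @return List of class \code{str_group_summary}: label, n, the values,
#'   the truncated median and the box-plot five-number summary.
#' @export
group_summary <- function(values, group_label) {
  bx <- boxplot_stats(values)
  structure(list(group_label = group_label, n = length(values),
                 values = values,
                 median_truncated = truncated_median(values),
                 quartiles = c(q1 = bx$q1, median = bx$median, q3 = bx$q3),
                 whiskers = c(low = bx$whisker_low, high = bx$whisker_high)),
            class = "str_group_summary")
}

#' @export
print.str_group_summary <- function(x, ...) {
  cat(sprintf("%s (n = %d): median %.2f [Q1 %.2f, Q3 %.2f], whiskers [%.2f, %.2f]\n",
              x$group_label, x$n, x$median_truncated, x$quartiles[["q1"]],
              x$quartiles[["q3"]], x$whiskers[["low"]], x$whiskers[["high"]]))
  invisible(x)
}

#' Tabulate group summaries
#'
#' @param summaries List of \code{\link{group_summary}} results.
#' @return Data frame with columns \code{group}, \code{n},
#'   \code{median_truncated}, \code{q1}, \code{q3}, \code{whisker_low},
#'   \code{whisker_high}.
#' @export
summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(group = s$group_label, n = s$n,
               median_truncated = s$median_truncated,
               q1 = s$quartiles[["q1"]], q3 = s$quartiles[["q3"]],
               whisker_low = s$whiskers[["low"]],
               whisker_high = s$whiskers[["high"]],
               stringsAsFactors = FALSE)
  }))
}
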