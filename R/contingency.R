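# 2x2 and r x k contingency statistics used to validate the risk score:
# odds ratio, Woolf (log-OR) confidence interval, Pearson chi-square and
# row percentages. The Woolf interval is the normal approximation on the
# log odds ratio with variance 1/a + 1/b + 1/c + 1/d.

as_2x2 <- function(x) {
  if (is.numeric(x) && is.null(dim(x)) && length(x) == 4) {
    x <- matrix(x, nrow = 2, byrow = TRUE)  # (a, b, c, d) row-wise
  }
  x <- as.matrix(x)
  if (!all(dim(x) == c(2, 2))) {
    stopf("a 2x2 table (matrix or length-4 vector a,b,c,d) is required",
          class = "pewrisk_invalid_input")
  }
  check_table(x)
  x
}

check_table <- function(m) {
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)) || any(m < 0)) {
    stopf("table counts must be finite non-negative numbers",
          class = "pewrisk_invalid_input")
  }
  if (sum(m) <= 0) {
    stopf("table grand total must be positive",
          class = "pewrisk_invalid_input")
  }
  invisible(m)
}

cell_names <- matrix(c("a", "b", "c", "d"), 2, 2, byrow = TRUE)

#' Odds ratio of a 2x2 contingency table
#'
#' Computes the cross-product odds ratio `(a*d)/(b*c)` for a table laid
#' out with rows as exposure levels (reference level first) and columns as
#' (low risk, high risk) or (no event, event).
#'
#' @param table A 2x2 matrix, or a length-4 numeric vector `(a, b, c, d)`
#'   read row-wise.
#' @param haldane If `TRUE`, apply the Haldane-Anscombe correction (add
#'   0.5 to every cell) before computing; by default a zero off-diagonal
#'   cell is an error naming the cell, never a silent correction.
#' @return The odds ratio (positive scalar).
#' @export
#' @examples
#' odds_ratio(c(261, 206, 168, 233))  # 1.757
odds_ratio <- function(table, haldane = FALSE) {
  m <- as_2x2(table)
  if (haldane) m <- m + 0.5
  zero <- which(m[cbind(c(1, 2), c(2, 1))] == 0)
  if (length(zero)) {
    stopf("zero count in cell '%s'; set haldane = TRUE for a continuity correction",
          c("b", "c")[zero[1]], class = "pewrisk_zero_cell")
  }
  (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
}

#' Woolf confidence interval for an odds ratio
#'
#' Normal-approximation interval on the log odds ratio:
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @inheritParams odds_ratio
#' @param level Confidence level as a fraction (default 0.95).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
#' @examples
#' woolf_ci(c(261, 206, 168, 233))  # 1.34 to 2.30
woolf_ci <- function(table, level = 0.95, haldane = FALSE) {
  m <- as_2x2(table)
  if (haldane) m <- m + 0.5
  if (any(m == 0)) {
    idx <- which(m == 0, arr.ind = TRUE)[1, ]
    stopf("zero count in cell '%s'; set haldane = TRUE for a continuity correction",
          cell_names[idx[1], idx[2]], class = "pewrisk_zero_cell")
  }
  if (length(level) != 1 || level <= 0 || level >= 1) {
    stopf("level must be a fraction in (0, 1)", class = "pewrisk_invalid_input")
  }
  log_or <- log((m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1]))
  se <- sqrt(sum(1 / m))
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = exp(log_or - z * se), upper = exp(log_or + z * se))
}

#' Pearson chi-square statistic of a contingency table
#'
#' Computes the Pearson statistic and its degrees of freedom for an r x k
#' table of counts, via [stats::chisq.test()] (Yates continuity correction
#' off by default, matching the uncorrected form used in the validation
#' tables).
#'
#' @param table An r x k matrix of counts (r, k >= 2), or `(a, b, c, d)`
#'   for a 2x2 table.
#' @param correct Apply the Yates continuity correction (2x2 only).
#' @return A list with `statistic`, `df` and `p_value`.
#' @export
pearson_chi2 <- function(table, correct = FALSE) {
  m <- if (is.null(dim(table)) && length(table) == 4) as_2x2(table)
       else as.matrix(table)
  check_table(m)
  if (any(dim(m) < 2)) {
    stopf("contingency table needs at least 2 rows and 2 columns",
          class = "pewrisk_invalid_input")
  }
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stopf("degenerate table: an all-zero row or column",
          class = "pewrisk_degenerate_table")
  }
  ch <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ch$statistic),
       df = as.integer(unname(ch$parameter)),
       p_value = unname(ch$p.value))
}

#' Upper-tail chi-square p-value
#'
#' @param stat Non-negative chi-square statistic.
#' @param df Degrees of freedom (>= 1).
#' @return Upper-tail probability `P(X^2 >= stat)`.
#' @export
chi2_pvalue <- function(stat, df) {
  check_numeric(stat, "stat", lower = 0)
  check_numeric(df, "df", lower = 1)
  stats::pchisq(stat, df, lower.tail = FALSE)
}

#' Row percentages of a contingency table
#'
#' Divides each cell by its row total, the presentation used in the
#' published validation tables (each exposure row shown as percent low
#' risk vs percent high risk).
#'
#' @param table An r x k matrix of counts with strictly positive row
#'   totals, or `(a, b, c, d)` for a 2x2 table.
#' @return Matrix of fractions; each row sums to 1.
#' @export
#' @examples
#' row_percentages(matrix(c(168, 233), 1))  # 0.419 0.581
row_percentages <- function(table) {
  m <- if (is.null(dim(table)) && length(table) == 4) as_2x2(table)
       else as.matrix(table)
  check_table(m)
  if (any(rowSums(m) == 0)) {
    stopf("degenerate row: zero row total", class = "pewrisk_degenerate_table")
  }
  out <- sweep(m, 1, rowSums(m), "/")
  attributes(out) <- attributes(out)[c("dim", "dimnames")]
  out
}

#' Full effect estimate for a contingency table
#'
#' Bundles the odds ratio, Woolf confidence interval and Pearson
#' chi-square test into one row, the unit of the validation report. For
#' tables larger than 2x2 (e.g. a 3-level factor vs risk group) the odds
#' ratio and interval are `NA` and only the chi-square test is reported.
#'
#' @inheritParams pearson_chi2
#' @param conf_level Confidence level for the Woolf interval.
#' @param haldane Continuity correction for zero cells, see [odds_ratio()].
#' @return One-row data frame: `odds_ratio`, `ci_low`, `ci_high`,
#'   `conf_level`, `chi2_stat`, `df`, `p_value`.
#' @export
effect_estimate <- function(table, conf_level = 0.95, correct = FALSE,
                            haldane = FALSE) {
  m <- if (is.null(dim(table)) && length(table) == 4) as_2x2(table)
       else as.matrix(table)
  ch <- pearson_chi2(m, correct = correct)
  if (all(dim(m) == c(2, 2))) {
    or <- odds_ratio(m, haldane = haldane)
    ci <- woolf_ci(m, level = conf_level, haldane = haldane)
  } else {
    or <- NA_real_
    ci <- c(lower = NA_real_, upper = NA_real_)
  }
  data.frame(odds_ratio = or, ci_low = unname(ci["lower"]),
             ci_high = unname(ci["upper"]), conf_level = conf_level,
             chi2_stat = ch$statistic, df = ch$df, p_value = ch$p_value)
}
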