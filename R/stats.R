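#' Paired t-test
#'
#' Paired Student t on matched samples. The one-tailed p-value tests the
#' alternative `mean(x - y) > 0`.
#'
#' @param x,y numeric vectors of equal length (n >= 2).
#' @param tails `"one"` or `"two"`.
#' @return list of class `test_result`: statistic, df, p_value, tails, flavor.
#' @export
paired_t <- function(x, y, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (length(x) != length(y)) stop("paired_t: unequal lengths")
  if (length(x) < 2) stop("paired_t: need n >= 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0)
    stop("paired_t: degenerate input (zero-variance differences)")
  tt <- stats::t.test(x, y, paired = TRUE,
                      alternative = if (tails == "one") "greater"
                                    else "two.sided")
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              tails, "paired")
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sample t with Satterthwaite degrees of freedom. The
#' one-tailed p-value tests the alternative `mean(x) > mean(y)`.
#'
#' @inheritParams paired_t
#' @return a `test_result` (flavor `"welch"`).
#' @export
welch_t <- function(x, y, tails = c("one", "two")) {
  tails <- match.arg(tails)
  if (length(x) < 2 || length(y) < 2) stop("welch_t: need n >= 2 per sample")
  if (stats::sd(x) == 0 && stats::sd(y) == 0)
    stop("welch_t: degenerate input (both samples constant)")
  tt <- stats::t.test(x, y, var.equal = FALSE,
                      alternative = if (tails == "one") "greater"
                                    else "two.sided")
  test_result(unname(tt$statistic), unname(tt$parameter), tt$p.value,
              tails, "welch")
}

test_result <- function(statistic, df, p_value, tails, flavor) {
  stopifnot(p_value >= 0, p_value <= 1, df > 0)
  structure(list(statistic = statistic, df = df, p_value = p_value,
                 tails = tails, flavor = flavor),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s t-test (%s-tailed): t = %.4f, df = %.3f, p = %.4g %s\n",
              x$flavor, x$tails, x$statistic, x$df, x$p_value,
              significance_stars(x$p_value)))
  invisible(x)
}

#' Significance stars
#'
#' `***` for p < 0.001, `**` for p < 0.01, `*` for p < 0.05, else `ns`.
#'
#' @param p p-value(s).
#' @return character vector.
#' @export
significance_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Box-plot summary
#'
#' Quartiles by linear interpolation (type 7); whiskers at one IQR beyond
#' the quartile box (`q1 - IQR`, `q3 + IQR`), not clamped to the data.
#'
#' @param values numeric vector (n >= 1).
#' @return list: q1, median, q3, whisker_lo, whisker_hi, n.
#' @export
box_summary <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("box_summary: empty input")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  list(q1 = q[1], median = q[2], q3 = q[3],
       whisker_lo = q[1] - iqr, whisker_hi = q[3] + iqr,
       n = length(values))
}
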