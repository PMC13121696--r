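#' Welch two-sample t-test from summary statistics
#'
#' Welch's unequal-variance t-test computed directly from the group
#' summaries, so printed "mean +/- SD, n" results can be re-tested without
#' raw data: `t = (mean_b - mean_a) / sqrt(sd_a^2/n_a + sd_b^2/n_b)` with
#' Welch-Satterthwaite degrees of freedom and a two-sided p from the
#' t-distribution. Reduces exactly to the pooled t-test for equal variances
#' and equal n. The two-sided p is symmetric under group swap.
#'
#' @param mean_a,sd_a,n_a Summary statistics of group A.
#' @param mean_b,sd_b,n_b Summary statistics of group B.
#' @return List of class `crush_htest`: `statistic` (t), `df`, `p_value`,
#'   `estimate` (mean difference b - a), `method`.
#' @export
#' @examples
#' welch_t(52.6, 31.3, 9, 110.4, 96.4, 21)
welch_t <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  assert_that(n_a >= 2 && n_b >= 2, "both groups need n >= 2")
  assert_that(sd_a >= 0 && sd_b >= 0, "standard deviations must be >= 0")
  va <- sd_a^2 / n_a
  vb <- sd_b^2 / n_b
  if (va + vb == 0) abort("both group variances are zero; t statistic undefined")
  tstat <- (mean_b - mean_a) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  structure(list(statistic = tstat, df = df,
                 p_value = 2 * pt(-abs(tstat), df),
                 estimate = mean_b - mean_a,
                 method = "Welch two-sample t-test (summary statistics)"),
            class = "crush_htest")
}

validate_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  assert_that(all(counts >= 0) && all(counts == round(counts)),
              "2x2 cells must be non-negative integers")
  assert_that(sum(counts) > 0, "2x2 table total must be positive")
  invisible(TRUE)
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact two-sided test by full hypergeometric enumeration with margins
#' fixed: the p-value is the sum of the probabilities of all tables in the
#' support whose probability does not exceed that of the observed table
#' (the probability-mass definition of two-sidedness; a relative tolerance
#' of 1e-7 guards ties against floating-point noise). A zero margin leaves
#' only one attainable table, so p = 1 by convention.
#'
#' @param a,b,c,d Cell counts, row-wise: `[[a, b], [c, d]]`.
#' @return List of class `crush_htest` with `p_value`, `odds_ratio`
#'   (sample ad/bc), `method`.
#' @export
#' @examples
#' fisher_exact_2x2(12, 9, 1, 8)
fisher_exact_2x2 <- function(a, b, c, d) {
  validate_2x2(a, b, c, d)
  m <- a + b        # row 1 margin
  n2 <- c + d       # row 2 margin
  k <- a + c        # column 1 margin
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) {
    p <- 1
  } else {
    support <- max(0, k - n2):min(k, m)
    probs <- dhyper(support, m, n2, k)
    p_obs <- dhyper(a, m, n2, k)
    p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  structure(list(statistic = NA_real_, df = NA_real_, p_value = p,
                 estimate = (a * d) / (b * c),
                 method = "Fisher exact test (two-sided, probability-mass rule)"),
            class = "crush_htest")
}

#' Chi-square test for a 2x2 table
#'
#' `X^2 = N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, optionally with the Yates
#' continuity correction (`N (|ad - bc| - N/2)^2 / ...`, floored at zero),
#' referred to chi-square with 1 df.
#'
#' @inheritParams fisher_exact_2x2
#' @param yates Apply the continuity correction.
#' @return List of class `crush_htest` with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_2x2(12, 9, 1, 8)
chi_square_2x2 <- function(a, b, c, d, yates = FALSE) {
  validate_2x2(a, b, c, d)
  N <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("chi-square test undefined: a margin is zero")
  num <- abs(a * d - b * c)
  if (yates) num <- max(0, num - N / 2)
  stat <- N * num^2 / prod(margins)
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, 1, lower.tail = FALSE),
                 estimate = (a * d) / (b * c),
                 method = if (yates) "Pearson chi-square (Yates-corrected)" else
                   "Pearson chi-square"),
            class = "crush_htest")
}

#' Sidak multiplicity adjustment
#'
#' `p_adj = 1 - (1 - p)^m` for `m` comparisons, clipped to `[0, 1]`;
#' monotone in both `p` and `m`. Computed via `expm1`/`log1p` so tiny raw
#' p-values are not lost to cancellation.
#'
#' @param p Raw p-value(s) in `[0, 1]`.
#' @param m Number of comparisons in the family (integer >= 1); never
#'   inferred.
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' sidak_adjust(0.01, 7)
sidak_adjust <- function(p, m) {
  assert_prob(p, "p")
  assert_that(length(m) == 1 && m >= 1 && m == round(m),
              "`m` must be a single integer >= 1")
  pmin(1, pmax(0, -expm1(m * log1p(-p))))
}

#' Median and interquartile range
#'
#' Quartiles by linear interpolation between order statistics (R's default
#' type-7 quantile rule), the convention used for "median (25th, 75th
#' percentile)" summaries.
#'
#' @param values Non-empty numeric vector.
#' @return One-row tibble `median`, `q25`, `q75`, `n`.
#' @export
#' @examples
#' median_iqr(1:9)
median_iqr <- function(values) {
  assert_that(length(values) > 0 && all(is.finite(values)),
              "`values` must be non-empty and finite")
  q <- quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  tibble::tibble(median = q[2], q25 = q[1], q75 = q[3], n = length(values))
}

#' @export
print.crush_htest <- function(x, ...) {
  cat("<", x$method, ">\n", sep = "")
  if (!is.na(x$statistic)) {
    cat(sprintf("  statistic = %.4f, df = %.4g, ", x$statistic, x$df))
  } else cat("  ")
  cat(sprintf("p = %.4g\n", x$p_value))
  invisible(x)
}

#' @rdname welch_t
#' @param x A `crush_htest`.
#' @param ... Unused.
#' @export
tidy.crush_htest <- function(x, ...) {
  tibble::tibble(method = x$method, statistic = x$statistic, df = x$df,
                 p_value = x$p_value, estimate = x$estimate)
}

#' @rdname welch_t
#' @export
glance.crush_htest <- function(x, ...) tidy(x)
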