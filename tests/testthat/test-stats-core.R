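test_that("Welch test from summaries matches t.test on raw data and handles edge cases", {
  # identical groups -> t = 0, p = 1
  eq <- welch_t(5, 2, 10, 5, 2, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  # oracle: stats::t.test on raw vectors, then summarized
  set.seed(2)
  x <- rnorm(9, 50, 30); y <- rnorm(21, 110, 90)
  ref <- t.test(y, x)
  got <- welch_t(mean(x), sd(x), 9, mean(y), sd(y), 21)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
  # equal variance, equal n: reduces to the pooled t-test
  pooled <- t.test(y[1:9], x, var.equal = TRUE)
  w <- welch_t(mean(x), sd(x), 9, mean(y[1:9]), sd(x), 9)
  tp <- (mean(y[1:9]) - mean(x)) / (sd(x) * sqrt(2 / 9))
  expect_equal(w$statistic, tp, tolerance = 1e-10)
  expect_equal(w$df, 16)
  # symmetry under group swap
  expect_equal(welch_t(1, 2, 5, 3, 4, 8)$p_value,
               welch_t(3, 4, 8, 1, 2, 5)$p_value, tolerance = 1e-12)
  expect_error(welch_t(1, 0, 5, 2, 0, 5), "variances")
})

test_that("printed porphyrin summary reproduces the reported group difference", {
  w <- welch_t(52.6, 31.3, 9, 110.4, 96.4, 21)
  expect_equal(w$statistic, 2.4615, tolerance = 1e-4)
  expect_equal(round(w$p_value, 2), 0.02)
})

test_that("Fisher exact enumeration matches fisher.test and hand-computable tables", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1.0)
  # full enumeration over support x in [4, 13]
  expect_equal(fisher_exact_2x2(12, 9, 1, 8)$p_value,
               fisher.test(matrix(c(12, 1, 9, 8), 2))$p.value, tolerance = 1e-10)
  # two extreme tables only: p = 2 / C(20, 10)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10)$p_value, 2 / choose(20, 10),
               tolerance = 1e-12)
  # random-table agreement with the oracle
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6), 2)
    expect_equal(fisher_exact_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])$p_value,
                 fisher.test(m)$p.value, tolerance = 1e-9)
  }
  # zero margin -> p = 1 by convention
  expect_equal(fisher_exact_2x2(0, 0, 3, 4)$p_value, 1)
})

test_that("hypergeometric probabilities over the full support sum to one", {
  for (tab in list(c(12, 9, 1, 8), c(3, 0, 2, 7), c(10, 10, 10, 10))) {
    m <- tab[1] + tab[2]; n2 <- tab[3] + tab[4]; k <- tab[1] + tab[3]
    support <- max(0, k - n2):min(k, m)
    expect_equal(sum(dhyper(support, m, n2, k)), 1, tolerance = 1e-12)
  }
})

test_that("chi-square statistic follows the closed formula, Yates never increases it", {
  expect_equal(chi_square_2x2(5, 5, 5, 5)$statistic, 0)
  expect_equal(chi_square_2x2(5, 5, 5, 5)$p_value, 1)
  expect_equal(chi_square_2x2(12, 9, 1, 8)$statistic,
               30 * 87^2 / (21 * 9 * 13 * 17), tolerance = 1e-12)
  # N-linearity at fixed proportions
  expect_equal(chi_square_2x2(24, 18, 2, 16)$statistic,
               2 * chi_square_2x2(12, 9, 1, 8)$statistic, tolerance = 1e-12)
  # oracle agreement
  ref <- suppressWarnings(chisq.test(matrix(c(12, 1, 9, 8), 2), correct = FALSE))
  expect_equal(chi_square_2x2(12, 9, 1, 8)$statistic, unname(ref$statistic),
               tolerance = 1e-10)
  refy <- suppressWarnings(chisq.test(matrix(c(12, 1, 9, 8), 2), correct = TRUE))
  expect_equal(chi_square_2x2(12, 9, 1, 8, yates = TRUE)$statistic,
               unname(refy$statistic), tolerance = 1e-10)
  set.seed(6)
  for (i in 1:15) {
    m <- matrix(rpois(4, 8) + 1, 2)
    expect_gte(chi_square_2x2(m[1], m[3], m[2], m[4])$statistic,
               chi_square_2x2(m[1], m[3], m[2], m[4], yates = TRUE)$statistic)
  }
  expect_error(chi_square_2x2(0, 0, 3, 4), "margin")
})

test_that("Sidak adjustment is exact, clipped, and monotone in p and m", {
  expect_equal(sidak_adjust(0.3, 1), 0.3)
  expect_equal(sidak_adjust(0.01, 7), 1 - 0.99^7, tolerance = 1e-12)
  expect_equal(sidak_adjust(0, 5), 0)
  expect_equal(sidak_adjust(1, 5), 1)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidak_adjust(p, 4)) >= 0))
  for (pp in c(0.001, 0.05, 0.4)) {
    adj <- vapply(1:10, function(m) sidak_adjust(pp, m), 0)
    expect_true(all(diff(adj) >= 0))
  }
  expect_error(sidak_adjust(0.05, 0), "m")
  expect_error(sidak_adjust(1.2, 3), "probabilities")
})

test_that("median and IQR use linear interpolation between order statistics", {
  m <- median_iqr(1:9)
  expect_equal(c(m$median, m$q25, m$q75), c(5, 3, 7))
  cv <- median_iqr(rep(4.2, 6))
  expect_equal(c(cv$median, cv$q25, cv$q75), rep(4.2, 3))
  set.seed(8)
  x <- rnorm(31)
  expect_equal(median_iqr(x), median_iqr(sample(x)))
  expect_error(median_iqr(numeric(0)), "non-empty")
})

test_that("Welch type-I error is calibrated on unequal-variance normals", {
  set.seed(99)
  n_sim <- 5000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    x <- rnorm(12, 0, 1); y <- rnorm(18, 0, 3)
    w <- welch_t(mean(x), sd(x), 12, mean(y), sd(y), 18)
    rej[i] <- w$p_value < 0.05
  }
  bounds <- qbinom(c(0.005, 0.995), n_sim, 0.05) / n_sim
  expect_gte(mean(rej), bounds[1])
  expect_lte(mean(rej), bounds[2])
})
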