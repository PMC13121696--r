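# vectorized two-sided p-values for 2x2 tables built from two binomial arms.
# test = "chi_square": uncorrected Pearson; "fisher": exact; "auto":
# chi-square with exact substitution when any expected cell < 5 or a margin
# is zero (a degenerate table never rejects: p = 1).
two_arm_p_values <- function(x1, n1, x2, n2, test) {
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  N <- n1 + n2
  c1 <- a + c; c2 <- b + d
  p <- rep(1, length(a))
  margin_ok <- c1 > 0 & c2 > 0
  chi_idx <- margin_ok
  if (test != "chi_square") {
    min_exp <- pmin(n1 * c1, n1 * c2, n2 * c1, n2 * c2) / N
    fisher_idx <- margin_ok & (test == "fisher" | min_exp < 5)
    chi_idx <- margin_ok & !fisher_idx
    if (any(fisher_idx)) {
      p[fisher_idx] <- vapply(which(fisher_idx), function(i) {
        fisher_exact_2x2(a[i], b[i], c[i], d[i])$p_value
      }, 0)
    }
  }
  if (any(chi_idx)) {
    stat <- N * (a[chi_idx] * d[chi_idx] - b[chi_idx] * c[chi_idx])^2 /
      (n1 * n2 * c1[chi_idx] * c2[chi_idx])
    p[chi_idx] <- pchisq(stat, 1, lower.tail = FALSE)
  }
  p
}

#' Simulate one two-arm binary-outcome trial
#'
#' Draws per-arm binomial recovery counts, applies the chosen 2x2 test, and
#' rejects when the two-sided p-value is strictly below the significance
#' level.
#'
#' @param n_treat,n_ctrl Subjects per arm (>= 1).
#' @param p_treat,p_ctrl True recovery probabilities per arm.
#' @param test `"chi_square"` (uncorrected), `"fisher"`, or `"auto"`
#'   (chi-square with exact substitution when any expected cell is < 5).
#' @param sig_level Two-sided significance level.
#' @return List: `reject`, `p_value`, `x_treat`, `x_ctrl`.
#' @export
#' @examples
#' set.seed(1)
#' simulate_trial(62, 62, 0.571, 0.111)
simulate_trial <- function(n_treat, n_ctrl, p_treat, p_ctrl,
                           test = c("auto", "chi_square", "fisher"),
                           sig_level = 0.01) {
  test <- match.arg(test)
  assert_that(n_treat >= 1 && n_ctrl >= 1, "arm sizes must be >= 1")
  assert_prob(c(p_treat, p_ctrl), "p_treat/p_ctrl")
  assert_that(sig_level > 0 && sig_level < 1, "`sig_level` must lie in (0, 1)")
  x1 <- rbinom(1, n_treat, p_treat)
  x2 <- rbinom(1, n_ctrl, p_ctrl)
  p <- two_arm_p_values(x1, n_treat, x2, n_ctrl, test)
  list(reject = p < sig_level, p_value = p, x_treat = x1, x_ctrl = x2)
}

#' Monte Carlo power curve for a two-arm binary-recovery trial
#'
#' For every total sample size on the grid (1:1 allocation), simulates
#' `reps_per_n` trials, records the rejection fraction at `sig_level`, fits a
#' monotone (isotonic) regression of power against n, and reports the
#' smallest grid n whose fitted power reaches `power_target` (flagged
#' out-of-range when the target is not reached on the grid). Fully seeded:
#' identical configuration and seed give an identical curve.
#'
#' @param p_treat,p_ctrl True per-arm recovery probabilities (defaults are
#'   the observed rapid-recovery proportions 0.571 and 0.111).
#' @param n_grid Total sample sizes (even, 1:1 allocation).
#' @param reps_per_n Simulated trials per grid point.
#' @param sig_level Two-sided significance level (default 0.01).
#' @param power_target Target power (default 0.90).
#' @param test Per-trial 2x2 test, as in [simulate_trial()].
#' @param seed RNG seed.
#' @return Tibble of class `crush_power_curve` (`n_total`, `n_per_arm`,
#'   `power_raw`, `power_fit`) with attributes `minimal_n_total`,
#'   `minimal_n_per_group`, `target_reached`, and the configuration.
#' @export
#' @examples
#' pc <- power_curve(n_grid = seq(20, 60, 10), reps_per_n = 50, seed = 7)
#' glance(pc)
power_curve <- function(p_treat = 0.571, p_ctrl = 0.111,
                        n_grid = seq(20, 200, 2), reps_per_n = 500,
                        sig_level = 0.01, power_target = 0.90,
                        test = c("auto", "chi_square", "fisher"),
                        seed = 1L) {
  test <- match.arg(test)
  assert_prob(c(p_treat, p_ctrl), "p_treat/p_ctrl")
  assert_that(all(n_grid %% 2 == 0), "`n_grid` totals must be even under 1:1 allocation")
  assert_that(reps_per_n >= 1, "`reps_per_n` must be >= 1")
  set.seed(seed)
  power_raw <- vapply(n_grid, function(n_tot) {
    n_arm <- n_tot / 2
    x1 <- rbinom(reps_per_n, n_arm, p_treat)
    x2 <- rbinom(reps_per_n, n_arm, p_ctrl)
    mean(two_arm_p_values(x1, n_arm, x2, n_arm, test) < sig_level)
  }, 0)
  power_fit <- if (length(n_grid) > 1) isoreg(n_grid, power_raw)$yf else power_raw
  reached <- which(power_fit >= power_target)
  minimal_n <- if (length(reached)) n_grid[reached[1]] else NA_integer_
  out <- tibble::tibble(n_total = n_grid, n_per_arm = n_grid / 2,
                        power_raw = power_raw, power_fit = power_fit)
  attr(out, "minimal_n_total") <- minimal_n
  attr(out, "minimal_n_per_group") <- minimal_n / 2
  attr(out, "target_reached") <- length(reached) > 0
  attr(out, "config") <- list(p_treat = p_treat, p_ctrl = p_ctrl,
                              reps_per_n = reps_per_n, sig_level = sig_level,
                              power_target = power_target, test = test,
                              seed = seed)
  class(out) <- c("crush_power_curve", class(out))
  out
}

#' Closed-form power of the two-proportion z-test
#'
#' Normal-approximation power for a two-sided comparison of two independent
#' proportions with equal arms (pooled variance under the null, unpooled
#' under the alternative); the analytic cross-check for the Monte Carlo
#' simulator. At `p1 = p2` it returns the significance level by
#' construction.
#'
#' @param p1,p2 True proportions.
#' @param n_per_arm Subjects per arm.
#' @param sig_level Two-sided significance level.
#' @return Power in `[0, 1]`.
#' @export
#' @examples
#' analytic_power_two_proportions(0.571, 0.111, 62, 0.01)
analytic_power_two_proportions <- function(p1, p2, n_per_arm, sig_level = 0.01) {
  assert_prob(c(p1, p2), "p1/p2")
  assert_that(n_per_arm >= 1, "`n_per_arm` must be >= 1")
  z_a <- qnorm(1 - sig_level / 2)
  pbar <- (p1 + p2) / 2
  se0 <- sqrt(2 * pbar * (1 - pbar) / n_per_arm)
  se1 <- sqrt(p1 * (1 - p1) / n_per_arm + p2 * (1 - p2) / n_per_arm)
  delta <- p1 - p2
  if (se1 == 0) return(as.numeric(abs(delta) > 0))
  pnorm((delta - z_a * se0) / se1) + pnorm((-delta - z_a * se0) / se1)
}

#' @export
print.crush_power_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<crush_power_curve> p = %.3f vs %.3f, alpha = %g, %d reps/n\n",
              cfg$p_treat, cfg$p_ctrl, cfg$sig_level, cfg$reps_per_n))
  if (isTRUE(attr(x, "target_reached"))) {
    cat(sprintf("  fitted power >= %.0f%% from n_total = %d (%d per group)\n",
                100 * cfg$power_target, attr(x, "minimal_n_total"),
                attr(x, "minimal_n_per_group")))
  } else {
    cat(sprintf("  power target %.0f%% not reached on the grid\n",
                100 * cfg$power_target))
  }
  NextMethod()
}

#' @rdname power_curve
#' @param x A `crush_power_curve`.
#' @param ... Unused.
#' @export
tidy.crush_power_curve <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname power_curve
#' @export
glance.crush_power_curve <- function(x, ...) {
  cfg <- attr(x, "config")
  tibble::tibble(minimal_n_total = attr(x, "minimal_n_total"),
                 minimal_n_per_group = attr(x, "minimal_n_per_group"),
                 target_reached = attr(x, "target_reached"),
                 p_treat = cfg$p_treat, p_ctrl = cfg$p_ctrl,
                 sig_level = cfg$sig_level, power_target = cfg$power_target,
                 reps_per_n = cfg$reps_per_n)
}

#' Plot a simulated power curve
#'
#' Raw rejection fractions with the monotone fit and the power target.
#'
#' @param object A `crush_power_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crush_power_curve <- function(object, ...) {
  cfg <- attr(object, "config")
  ggplot2::ggplot(object, ggplot2::aes(.data$n_total, .data$power_raw)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$power_fit), colour = "steelblue") +
    ggplot2::geom_hline(yintercept = cfg$power_target, linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "Total sample size", y = "Power",
                  title = sprintf("Monte Carlo power (alpha = %g)", cfg$sig_level))
}
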