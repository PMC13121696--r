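#' Detect protocolized hyperkalemia interventions in a potassium series
#'
#' One intervention per scheduled measurement strictly above the treatment
#' threshold (a draw exactly at the threshold does not trigger). Monitoring
#' between scheduled draws is not modeled: the event time is the draw time.
#'
#' @param time_h Measurement times (h), strictly increasing.
#' @param potassium_mmol_l Blood potassium at those times.
#' @param threshold Treatment threshold (mmol/L), default 5.0.
#' @return Tibble `time_h`, `trigger_potassium_mmol_l`, one row per event.
#' @export
#' @examples
#' detect_interventions(c(0, 6, 12, 24), c(4.2, 5.3, 4.8, 5.1))
detect_interventions <- function(time_h, potassium_mmol_l, threshold = 5.0) {
  assert_that(length(time_h) == length(potassium_mmol_l),
              "times and potassium must have equal length")
  assert_increasing(time_h, "time_h")
  hit <- potassium_mmol_l > threshold
  tibble::tibble(time_h = time_h[hit],
                 trigger_potassium_mmol_l = potassium_mmol_l[hit])
}

#' Ratio of median intervention counts between two groups
#'
#' @param group_a_counts,group_b_counts Per-subject intervention counts for
#'   the reference and comparison groups.
#' @param digits Decimals of the reported ratio (default 1, the convention
#'   used for "x-fold more interventions" statements).
#' @return `median(b) / median(a)` rounded to `digits`.
#' @export
#' @examples
#' intervention_ratio(c(4, 7, 8), c(8, 10, 12))
intervention_ratio <- function(group_a_counts, group_b_counts, digits = 1) {
  assert_that(length(group_a_counts) > 0 && length(group_b_counts) > 0,
              "count vectors must be non-empty")
  ma <- median(group_a_counts)
  if (ma == 0) abort("median of the reference group is zero; ratio undefined")
  round(median(group_b_counts) / ma, digits)
}

#' Time to first event per subject, right-censored
#'
#' Builds a survival dataset (one row per subject) from per-subject event
#' lists: time to the first event, or the censoring time (48 h or death)
#' when no event occurred.
#'
#' @param cohort A `crush_cohort`.
#' @param censor_time_h Administrative censoring time (default the last
#'   scheduled draw).
#' @return Tibble `animal_id`, `group`, `time_h`, `event` (1 = observed).
#' @export
time_to_first_intervention <- function(cohort, censor_time_h = NULL) {
  stopifnot(inherits(cohort, "crush_cohort"))
  censor_time_h <- censor_time_h %||% max(cohort$study$chem_times_h)
  firsts <- cohort$events |>
    dplyr::group_by(.data$animal_id) |>
    dplyr::summarise(first_time = min(.data$time_h), .groups = "drop")
  cohort$animals |>
    dplyr::left_join(firsts, by = "animal_id") |>
    dplyr::transmute(.data$animal_id, .data$group,
                     time_h = dplyr::coalesce(.data$first_time, censor_time_h),
                     event = as.integer(!is.na(.data$first_time)))
}

#' Kaplan-Meier product-limit estimator
#'
#' From-first-principles product-limit estimate per group:
#' `S(t) = prod over event times t_i <= t of (1 - d_i / n_i)` with
#' right-censoring (censored subjects leave the risk set just after their
#' censoring time; ties between events and censorings at the same time keep
#' the censored subjects at risk for the event, the standard convention).
#' With no censoring the estimator equals the empirical survival function.
#'
#' @param data Tibble with columns `time_h` (>= 0), `event` (1 = event
#'   observed, 0 = censored) and optionally `group`.
#' @return Tibble of class `crush_km`: `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`, including a time-zero row at survival 1.
#' @export
#' @examples
#' km_estimate(tibble::tibble(time_h = c(2, 3, 4, 4, 7),
#'                            event = c(0, 1, 1, 1, 0)))
km_estimate <- function(data) {
  require_columns(data, c("time_h", "event"), "survival data")
  if (any(data$time_h < 0)) abort("event/censoring times must be >= 0")
  if (!"group" %in% names(data)) data$group <- "all"
  out <- data |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(function(d, key) {
      stopifnot(nrow(d) >= 1)
      times <- sort(unique(d$time_h))
      n_risk <- vapply(times, function(tt) sum(d$time_h >= tt), 0)
      n_event <- vapply(times, function(tt) sum(d$time_h == tt & d$event == 1), 0)
      n_censor <- vapply(times, function(tt) sum(d$time_h == tt & d$event == 0), 0)
      surv <- cumprod(1 - n_event / n_risk)
      tibble::tibble(time = c(0, times),
                     n_risk = c(nrow(d), n_risk),
                     n_event = c(0, n_event),
                     n_censor = c(0, n_censor),
                     survival = c(1, surv))
    }) |>
    dplyr::ungroup()
  class(out) <- c("crush_km", class(out))
  out
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank statistic computed from first principles:
#' at each distinct event time the expected number of events in group 1 is
#' allocated from the pooled risk set, tied events are all counted at that
#' time, and the statistic `(O1 - E1)^2 / V` is referred to chi-square with
#' 1 df. Invariant under group relabeling and under strictly monotone time
#' transformations.
#'
#' @param data Tibble with `time_h`, `event` (1 = observed), `group` (exactly
#'   two levels).
#' @return List of class `crush_logrank`: `statistic`, `df`, `p_value`,
#'   `observed`, `expected` (per group), `direction` (the group with more
#'   events than expected, i.e. earlier events).
#' @export
logrank_test <- function(data) {
  require_columns(data, c("time_h", "event", "group"), "survival data")
  if (any(data$time_h < 0)) abort("event/censoring times must be >= 0")
  grp <- sort(unique(data$group))
  assert_that(length(grp) == 2, "log-rank test requires exactly two groups")
  if (sum(data$event) == 0) abort("no events observed; log-rank statistic undefined")
  ev_times <- sort(unique(data$time_h[data$event == 1]))
  g1 <- data$group == grp[1]
  O1 <- 0; E1 <- 0; V <- 0
  for (tt in ev_times) {
    at_risk <- data$time_h >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(data$time_h == tt & data$event == 1)
    d1 <- sum(data$time_h == tt & data$event == 1 & g1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- (O1 - E1)^2 / V
  total_events <- sum(data$event)
  structure(list(
    statistic = stat, df = 1L, p_value = pchisq(stat, 1, lower.tail = FALSE),
    observed = setNames(c(O1, total_events - O1), grp),
    expected = setNames(c(E1, total_events - E1), grp),
    direction = if (O1 > E1) grp[1] else grp[2]
  ), class = "crush_logrank")
}

#' @export
print.crush_logrank <- function(x, ...) {
  cat("<log-rank test>\n")
  cat(sprintf("  chi-square = %.4f, df = %d, p = %.4g\n", x$statistic, x$df, x$p_value))
  cat(sprintf("  observed: %s | expected: %s | earlier events: %s\n",
              paste(sprintf("%s=%g", names(x$observed), x$observed), collapse = ", "),
              paste(sprintf("%s=%.2f", names(x$expected), x$expected), collapse = ", "),
              x$direction))
  invisible(x)
}

#' @rdname logrank_test
#' @param x A `crush_logrank`.
#' @param ... Unused.
#' @export
tidy.crush_logrank <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 direction = x$direction)
}

#' @rdname logrank_test
#' @export
glance.crush_logrank <- function(x, ...) tidy(x)

#' Step plot of Kaplan-Meier curves
#'
#' @param object A `crush_km`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.crush_km <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$survival,
                                       colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (h)", y = "Event-free fraction", colour = NULL)
}
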