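test_that("intervention detection counts strict threshold exceedances only", {
  ev <- detect_interventions(c(0, 6, 12, 24), c(4.2, 5.3, 4.8, 5.1))
  expect_equal(nrow(ev), 2)
  expect_equal(ev$time_h, c(6, 24))
  expect_equal(nrow(detect_interventions(c(0, 6), c(4.9, 5.0))), 0)  # boundary
  expect_equal(nrow(detect_interventions(c(0, 6), c(4.0, 4.5))), 0)
  expect_error(detect_interventions(c(6, 0), c(5.5, 5.5)), "increasing")
})

test_that("median intervention ratio reproduces the x-fold statements", {
  expect_equal(intervention_ratio(c(4, 7, 8), c(8, 10, 12)), 1.4)   # 10/7
  expect_equal(intervention_ratio(c(3, 4, 11), c(8, 10, 12)), 2.5)  # 10/4
  expect_equal(intervention_ratio(c(5, 6, 7), c(5, 6, 7)), 1.0)
  expect_error(intervention_ratio(c(0, 0, 0), c(1, 2, 3)), "zero")
})

test_that("product-limit estimator matches hand enumeration on the worked set", {
  km <- km_estimate(worked_survival())
  s_at <- function(tt) km$survival[max(which(km$time <= tt))]
  # risk set at t=3 is 4 (censoring at 2 removed one subject): S = 3/4
  expect_equal(s_at(3), 0.75)
  # t=4: 2 events among 3 at risk: S = 0.75 * (1/3) = 0.25
  expect_equal(s_at(4), 0.25)
  expect_equal(s_at(0), 1)
  expect_true(all(diff(km$survival) <= 0))
})

test_that("KM equals the empirical survival function without censoring, and edge cases hold", {
  tt <- c(1, 3, 3, 7, 9)
  km <- km_estimate(tibble::tibble(time_h = tt, event = 1))
  for (q in c(0.5, 2, 3, 8, 10)) {
    emp <- mean(tt > q)
    expect_equal(km$survival[max(which(km$time <= q))], emp)
  }
  # all censored -> S identically 1
  km0 <- km_estimate(tibble::tibble(time_h = c(48, 48, 48), event = 0))
  expect_true(all(km0$survival == 1))
  # single subject with an event -> drops to 0
  km1 <- km_estimate(tibble::tibble(time_h = 6, event = 1))
  expect_equal(km1$survival[km1$time == 6], 0)
  expect_error(km_estimate(tibble::tibble(time_h = -1, event = 1)), ">= 0")
})

test_that("KM and log-rank agree with the survival package to 1e-8 on fixtures", {
  skip_if_not_installed("survival")
  set.seed(17)
  d <- tibble::tibble(
    time_h = round(rexp(40, 1 / 20), 1) + 0.1,
    event = rbinom(40, 1, 0.7),
    group = rep(c("a", "b"), each = 20))
  # KM per group against survfit run on that group alone
  km <- km_estimate(d)
  for (g in c("a", "b")) {
    dg <- d[d$group == g, ]
    sf <- survival::survfit(survival::Surv(time_h, event) ~ 1, data = dg)
    ref <- stats::stepfun(sf$time, c(1, sf$surv))
    kg <- km[km$group == g & km$time > 0, ]
    expect_equal(kg$survival, ref(kg$time), tolerance = 1e-8)
  }
  # log-rank
  sd_ref <- survival::survdiff(survival::Surv(time_h, event) ~ group, data = d)
  lr <- logrank_test(d)
  expect_equal(lr$statistic, sd_ref$chisq, tolerance = 1e-8)
  expect_equal(lr$p_value, pchisq(sd_ref$chisq, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("log-rank is invariant to group relabeling and monotone time transforms", {
  set.seed(23)
  d <- tibble::tibble(time_h = rexp(30, 1 / 10), event = rbinom(30, 1, 0.8),
                      group = rep(c("a", "b"), 15))
  lr <- logrank_test(d)
  swapped <- dplyr::mutate(d, group = ifelse(group == "a", "b", "a"))
  expect_equal(logrank_test(swapped)$statistic, lr$statistic, tolerance = 1e-12)
  warped <- dplyr::mutate(d, time_h = log1p(time_h)^1.5)
  expect_equal(logrank_test(warped)$statistic, lr$statistic, tolerance = 1e-12)
})

test_that("clear separation rejects and flags the early group; no events errors", {
  d <- tibble::tibble(time_h = c(2, 3, 4, 5, 48, 48, 48, 48),
                      event = c(1, 1, 1, 1, 0, 0, 0, 0),
                      group = rep(c("a", "b"), each = 4))
  lr <- logrank_test(d)
  expect_lt(lr$p_value, 0.05)
  expect_equal(lr$direction, "a")
  expect_error(logrank_test(dplyr::mutate(d, event = 0)), "no events")
})

test_that("log-rank type-I error is calibrated under the null", {
  set.seed(77)
  n_sim <- 2000
  rej <- logical(n_sim)
  for (i in seq_len(n_sim)) {
    t_raw <- rexp(30, 1 / 15)
    d <- tibble::tibble(time_h = pmin(t_raw, 48),
                        event = as.integer(t_raw <= 48),
                        group = rep(c("a", "b"), each = 15))
    rej[i] <- logrank_test(d)$p_value < 0.05
  }
  bounds <- qbinom(c(0.005, 0.995), n_sim, 0.05) / n_sim
  expect_gte(mean(rej), bounds[1])
  expect_lte(mean(rej), bounds[2])
})

test_that("time to first intervention censors event-free animals at 48 h", {
  co <- generate_cohort(small_study(seed = 8))
  tte <- time_to_first_intervention(co)
  expect_equal(nrow(tte), nrow(co$animals))
  firsts <- co$events |>
    dplyr::group_by(animal_id) |>
    dplyr::summarise(first = min(time_h))
  for (i in seq_len(nrow(firsts))) {
    expect_equal(tte$time_h[tte$animal_id == firsts$animal_id[i]], firsts$first[i])
  }
  no_ev <- setdiff(tte$animal_id, firsts$animal_id)
  expect_true(all(tte$event[tte$animal_id %in% no_ev] == 0))
  expect_true(all(tte$time_h[tte$animal_id %in% no_ev] == 48))
})
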