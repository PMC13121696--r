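test_that("noiseless biexponential parameters are recovered to 1e-6 relative", {
  s <- biexp_series(A = 50, alpha = 0.15, B = 10, beta = 0.01)
  fit <- fit_two_compartment(s$t, s$c, dose_mg = 3235)
  expect_true(fit$converged)
  expect_false(fit$poor)
  expect_equal(fit$A_ug_ml, 50, tolerance = 1e-6)
  expect_equal(fit$alpha_per_min, 0.15, tolerance = 1e-6)
  expect_equal(fit$B_ug_ml, 10, tolerance = 1e-6)
  expect_equal(fit$beta_per_min, 0.01, tolerance = 1e-6)
})

test_that("simulated two-compartment series round-trips the generating GFR", {
  s <- simulate_iohexol_series(gfr_ml_min = 80, dose_mg = 3235, v_central_l = 3,
                               noise_cv = 0)
  fit <- estimate_gfr(s$offset_min, s$concentration_ug_ml, dose_mg = 3235)
  expect_equal(fit$gfr_ml_min, 80, tolerance = 1e-6)
})

test_that("closed-form AUC worked example: dose 3235 mg gives GFR 78.52 mL/min", {
  s <- biexp_series(A = 60, alpha = 0.05, B = 20, beta = 5e-4)
  fit <- fit_two_compartment(s$t, s$c, dose_mg = 3235)
  expect_equal(fit$auc_mg_min_per_l, 60 / 0.05 + 20 / 5e-4, tolerance = 1e-6)
  expect_equal(fit$gfr_ml_min, 3235 / 41200 * 1000, tolerance = 1e-6)
})

test_that("degenerate inputs are rejected with precondition errors", {
  t <- c(15, 30, 90, 120, 180, 240, 300)
  expect_error(fit_two_compartment(t, rep(0, 7), 1000), "positive")
  expect_error(fit_two_compartment(t[1:4], exp(-0.01 * t[1:4]), 1000), "at least 5")
  expect_error(fit_one_compartment(c(15, 30, 90), c(1, 2, 3), 1000), "decay")
  expect_error(fit_one_compartment(c(30, 15, 90), c(3, 2, 1), 1000), "increasing")
})

test_that("one-compartment fit is exact on noiseless exponentials: AUC = C0/k", {
  t <- c(15, 60, 200)
  fit <- fit_one_compartment(t, 10 * exp(-0.01 * t), dose_mg = 1000)
  expect_equal(fit$A_ug_ml, 10, tolerance = 1e-9)
  expect_equal(fit$alpha_per_min, 0.01, tolerance = 1e-9)
  expect_equal(fit$auc_mg_min_per_l, 1000, tolerance = 1e-9)
  expect_equal(fit$gfr_ml_min, 1000, tolerance = 1e-9)  # 1000 mg / 1000 mg*min/L = 1 L/min
})

test_that("monoexponential data trips the poor-fit criteria and the fallback recovers k and C0", {
  t <- c(15, 30, 90, 120, 180, 240, 300)
  c_mono <- 10 * exp(-0.01 * t)
  fit <- estimate_gfr(t, c_mono, dose_mg = 1000)
  expect_equal(fit$model_order, 1)
  expect_true(fit$fallback_used)
  expect_equal(fit$A_ug_ml, 10, tolerance = 1e-6)
  expect_equal(fit$alpha_per_min, 0.01, tolerance = 1e-6)
  # nested-model consistency: either model yields the same clearance
  two <- fit_two_compartment(t, c_mono, 1000)
  expect_equal(two$gfr_ml_min, fit$gfr_ml_min, tolerance = 1e-6)
})

test_that("GFR x AUC = dose holds for every returned fit", {
  set.seed(31)
  for (i in 1:25) {
    gfr <- runif(1, 20, 150)
    dose <- runif(1, 1000, 5000)
    s <- simulate_iohexol_series(gfr, dose, v_central_l = runif(1, 2, 5),
                                 noise_cv = 0.05, seed = i)
    fit <- estimate_gfr(s$offset_min, s$concentration_ug_ml, dose)
    expect_equal(fit$gfr_ml_min * fit$auc_mg_min_per_l / 1000, dose,
                 tolerance = 1e-9)
  }
})

test_that("scale and time-unit equivariance of the clearance estimate", {
  s <- simulate_iohexol_series(90, 3235, noise_cv = 0.03, seed = 4)
  fit <- estimate_gfr(s$offset_min, s$concentration_ug_ml, 3235)
  # concentration scale: c-fold concentrations -> c-fold AUC, 1/c-fold GFR
  fit2 <- estimate_gfr(s$offset_min, 2 * s$concentration_ug_ml, 3235)
  expect_equal(fit2$auc_mg_min_per_l, 2 * fit$auc_mg_min_per_l, tolerance = 1e-6)
  expect_equal(fit2$gfr_ml_min, fit$gfr_ml_min / 2, tolerance = 1e-6)
  # uniformly higher curves imply lower clearance
  fit3 <- estimate_gfr(s$offset_min, 1.3 * s$concentration_ug_ml, 3235)
  expect_lt(fit3$gfr_ml_min, fit$gfr_ml_min)
})

test_that("closed-form AUC agrees with trapezoid plus tail extrapolation within 0.5%", {
  # independent numerical oracle: dense trapezoid to the last sample, then a
  # terminal-slope tail C(T)/beta
  for (gfr in c(40, 80, 120)) {
    s <- simulate_iohexol_series(gfr, 3235, noise_cv = 0)
    fit <- fit_two_compartment(s$offset_min, s$concentration_ug_ml, 3235)
    tg <- seq(0, 300, by = 0.1)
    cg <- fit$A_ug_ml * exp(-fit$alpha_per_min * tg) +
      fit$B_ug_ml * exp(-fit$beta_per_min * tg)
    auc_num <- sum(diff(tg) * (cg[-1] + cg[-length(cg)]) / 2) +
      cg[length(cg)] / fit$beta_per_min
    expect_equal(fit$auc_mg_min_per_l, auc_num, tolerance = 5e-3)
  }
})

test_that("cohort-level fitting returns one row per injection with diagnostics", {
  co <- generate_cohort(small_study(seed = 6))
  fits <- fit_gfr(co$iohexol)
  expect_equal(nrow(fits), nrow(co$animals) * 3)
  expect_true(all(c("gfr_ml_min", "auc_mg_min_per_l", "fallback_used") %in% names(fits)))
  expect_true(all(fits$gfr_ml_min > 0))
})

test_that("inverse-variance weighting policy is accepted and changes the loss", {
  s <- simulate_iohexol_series(70, 3235, noise_cv = 0.08, seed = 12)
  fw <- fit_two_compartment(s$offset_min, s$concentration_ug_ml, 3235,
                            policy = gfr_policy(weighting = "inv_c2"))
  fu <- fit_two_compartment(s$offset_min, s$concentration_ug_ml, 3235)
  expect_true(fw$converged)
  expect_false(isTRUE(all.equal(fw$gfr_ml_min, fu$gfr_ml_min, tolerance = 1e-12)))
})
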