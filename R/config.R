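#' Study design configuration
#'
#' Describes the fixed design of a 48 h crush-syndrome experiment: group
#' sizes, the scheduled blood/urine chemistry draws, the iohexol injection
#' schedule with its post-dose sampling offsets, the iohexol dose, the
#' hyperkalemia treatment threshold, and the creatinine recovery fraction.
#' Study time zero is drug administration (30 min after impact); the baseline
#' draw therefore carries a negative time.
#'
#' @param group_sizes Named integer vector of animals per group. Names must be
#'   `no_impact`, `vehicle`, `cilastatin`.
#' @param animal_weight_kg Nominal animal weight (kg).
#' @param chem_times_h Scheduled chemistry sampling times in hours relative to
#'   drug administration; the first (negative) entry is the pre-impact
#'   baseline draw.
#' @param iohexol_injection_times_h Times (h) of intravenous iohexol
#'   injections.
#' @param iohexol_sample_offsets_min Post-injection blood sampling offsets
#'   (min).
#' @param iohexol_dose_mg Iohexol mass per injection (mg). The default is a
#'   5 mL bolus of a 647 mg/mL iohexol formulation (the 300 mg iodine/mL
#'   contrast product), i.e. 3235 mg.
#' @param k_threshold_mmol_l Blood potassium above which (strictly) a
#'   protocolized hyperkalemia intervention is triggered.
#' @param recovery_fraction Creatinine rapid-recovery threshold: recovery is
#'   a 48 h creatinine strictly below this fraction of the maximal creatinine.
#' @param impact_time_h Time of the crush impact (h, negative = before drug).
#' @param seed Master RNG seed for cohort generation.
#'
#' @return A list of class `crush_study_config`.
#' @export
#' @examples
#' study_config(seed = 1)
study_config <- function(group_sizes = c(no_impact = 6, vehicle = 9, cilastatin = 21),
                         animal_weight_kg = 40,
                         chem_times_h = c(-1, 0, 2, 6, 12, 18, 24, 48),
                         iohexol_injection_times_h = c(1, 19, 43),
                         iohexol_sample_offsets_min = c(15, 30, 90, 120, 180, 240, 300),
                         iohexol_dose_mg = 3235,
                         k_threshold_mmol_l = 5.0,
                         recovery_fraction = 0.70,
                         impact_time_h = -0.5,
                         seed = 1L) {
  groups <- c("no_impact", "vehicle", "cilastatin")
  assert_that(length(group_sizes) > 0 && !is.null(names(group_sizes)) &&
                all(names(group_sizes) %in% groups),
              "`group_sizes` must be named with no_impact/vehicle/cilastatin")
  full_sizes <- setNames(rep(0L, length(groups)), groups)
  full_sizes[names(group_sizes)] <- as.integer(pmax(group_sizes, 0))
  assert_increasing(chem_times_h, "chem_times_h")
  assert_increasing(iohexol_injection_times_h, "iohexol_injection_times_h")
  assert_increasing(iohexol_sample_offsets_min, "iohexol_sample_offsets_min")
  assert_positive(iohexol_dose_mg, "iohexol_dose_mg")
  assert_positive(animal_weight_kg, "animal_weight_kg")
  assert_that(recovery_fraction > 0 && recovery_fraction < 1,
              "`recovery_fraction` must lie in (0, 1)")
  structure(list(
    group_sizes = full_sizes,
    animal_weight_kg = animal_weight_kg,
    chem_times_h = chem_times_h,
    iohexol_injection_times_h = iohexol_injection_times_h,
    iohexol_sample_offsets_min = iohexol_sample_offsets_min,
    iohexol_dose_mg = iohexol_dose_mg,
    k_threshold_mmol_l = k_threshold_mmol_l,
    recovery_fraction = recovery_fraction,
    impact_time_h = impact_time_h,
    seed = as.integer(seed)
  ), class = "crush_study_config")
}

#' Generative effect-size configuration for synthetic cohorts
#'
#' Parameters of the synthetic data-generating model: baseline GFR
#' distribution, per-group injury severity and recovery kinetics, per-group
#' rapid-recovery probabilities, creatinine mass-balance constants, creatine
#' kinase (CK) and potassium trajectory parameters, the potassium drop applied
#' by each protocolized intervention, iohexol two-compartment constants and
#' assay noise, and urinary myoglobin/porphyrin excretion multipliers.
#'
#' Defaults reproduce the statistical structure of the source study: rapid
#' recovery probabilities 0.571 (cilastatin) and 0.111 (vehicle); CK rising
#' along a saturating curve to ~16,700 IU/L at 48 h in impacted animals (about
#' half that without impact); potassium coupled to CK so every impacted animal
#' crosses the 5.0 mmol/L treatment threshold by the 6 h draw; a 2.1-fold
#' cilastatin multiplier on creatinine-normalized urinary porphyrin excretion.
#'
#' @param baseline_gfr_ml_min Length-2 vector `c(mean, sd)` of pre-injury GFR.
#' @param injury_gfr_drop_fraction Named per-group fraction of baseline GFR
#'   lost at the injured nadir (0 = no injury).
#' @param gfr_decline_tau_h Time constant (h) of the exponential post-impact
#'   GFR decline.
#' @param recovery_start_h Hour at which linear GFR recovery begins.
#' @param recovery_rate_per_h Named per-group GFR recovery slope (mL/min per
#'   h) for animals drawn as rapid recoverers.
#' @param nonrecovery_rate_per_h Recovery slope for non-recovering animals.
#' @param recovery_probability Named per-group probability of rapid recovery.
#' @param creatinine_production_rate_mg_h Creatinine generation G (mg/h).
#' @param creatinine_volume_l Creatinine distribution volume V (L).
#' @param creatinine_noise_cv Multiplicative lognormal CV of creatinine assay.
#' @param ck_baseline_iu_l Baseline plasma CK (IU/L).
#' @param ck_plateau_iu_l Named per-group CK plateau (IU/L) of the saturating
#'   post-impact rise.
#' @param ck_tau_h Time constant (h) of the CK rise.
#' @param ck_noise_cv Lognormal CV of CK measurements.
#' @param k_baseline_mmol_l Baseline blood potassium (mmol/L).
#' @param k_per_ck Potassium rise per unit CK (mmol/L per IU/L); couples the
#'   hyperkalemia trajectory to muscle injury.
#' @param k_noise_sd Additive Gaussian SD of potassium measurements
#'   (truncated at zero).
#' @param intervention_k_drop_mmol_l Persistent potassium drop applied by each
#'   protocolized hyperkalemia intervention.
#' @param iohexol_noise_cv Lognormal CV of iohexol concentration measurements.
#' @param iohexol_v_central_l Central compartment volume V1 (L).
#' @param iohexol_k12_per_min,iohexol_k21_per_min Inter-compartment micro-rate
#'   constants (1/min).
#' @param myoglobin_fe_multiplier Named per-group multiplier on the fractional
#'   excretion of myoglobin and on creatinine-normalized porphyrin excretion.
#' @param plasma_mb_per_ck Plasma myoglobin (ng/mL) per unit CK (IU/L).
#' @param fe_mb_base Baseline fractional excretion of myoglobin.
#' @param porphyrin_cr_ratio Baseline urinary porphyrin/creatinine ratio
#'   (per-sample, before group multipliers).
#' @param porphyrin_noise_cv,urine_noise_cv Lognormal CVs of urine measures.
#'
#' @return A list of class `crush_effect_config`.
#' @export
effect_config <- function(baseline_gfr_ml_min = c(mean = 110, sd = 10),
                          injury_gfr_drop_fraction = c(no_impact = 0.45, vehicle = 0.60, cilastatin = 0.60),
                          gfr_decline_tau_h = 4,
                          recovery_start_h = 24,
                          recovery_rate_per_h = c(no_impact = 2.0, vehicle = 2.0, cilastatin = 2.75),
                          nonrecovery_rate_per_h = 0.3,
                          recovery_probability = c(no_impact = 0.5, vehicle = 0.111, cilastatin = 0.571),
                          creatinine_production_rate_mg_h = 80,
                          creatinine_volume_l = 20,
                          creatinine_noise_cv = 0.03,
                          ck_baseline_iu_l = 100,
                          ck_plateau_iu_l = c(no_impact = 8000, vehicle = 16700, cilastatin = 16700),
                          ck_tau_h = 20,
                          ck_noise_cv = 0.10,
                          k_baseline_mmol_l = 4.0,
                          k_per_ck = 2.5e-4,
                          k_noise_sd = 0.10,
                          intervention_k_drop_mmol_l = 0.5,
                          iohexol_noise_cv = 0.05,
                          iohexol_v_central_l = 3.5,
                          iohexol_k12_per_min = 0.05,
                          iohexol_k21_per_min = 0.02,
                          myoglobin_fe_multiplier = c(no_impact = 1, vehicle = 1, cilastatin = 2.1),
                          plasma_mb_per_ck = 0.2,
                          fe_mb_base = 0.002,
                          porphyrin_cr_ratio = 1.1,
                          porphyrin_noise_cv = 0.25,
                          urine_noise_cv = 0.10) {
  assert_prob(recovery_probability, "recovery_probability")
  assert_prob(injury_gfr_drop_fraction, "injury_gfr_drop_fraction")
  assert_that(all(c(creatinine_noise_cv, ck_noise_cv, iohexol_noise_cv,
                    porphyrin_noise_cv, urine_noise_cv) >= 0),
              "noise CVs must be >= 0")
  assert_positive(baseline_gfr_ml_min[["mean"]], "baseline_gfr_ml_min[mean]")
  assert_positive(creatinine_volume_l, "creatinine_volume_l")
  assert_positive(intervention_k_drop_mmol_l, "intervention_k_drop_mmol_l")
  assert_positive(iohexol_v_central_l, "iohexol_v_central_l")
  assert_that(all(c(iohexol_k12_per_min, iohexol_k21_per_min) >= 0),
              "inter-compartment rates must be >= 0")
  structure(as.list(environment()), class = "crush_effect_config")
}

#' Model-selection policy for GFR estimation
#'
#' Controls when a two-compartment iohexol fit is declared poor and the
#' one-compartment fallback is used, and the least-squares weighting.
#' A fit is poor when any of: the optimizer fails to converge; a parameter is
#' pinned within `bound_tol` of its positivity bound; the fast/slow phase
#' ratio alpha/beta falls below `min_phase_ratio` (phases unidentifiable); or
#' AIC prefers the one-compartment model (no small-sample correction: the
#' seven-sample design leaves a single residual degree of freedom for the
#' biexponential, where the AICc correction diverges).
#'
#' @param min_phase_ratio Minimum identifiable alpha/beta ratio.
#' @param use_aic Compare models by AIC.
#' @param bound_tol Distance from the positivity bound at which a parameter
#'   counts as pinned.
#' @param weighting `"none"` (unweighted least squares on linear
#'   concentrations) or `"inv_c2"` (1/C^2 weights).
#' @return A list of class `crush_gfr_policy`.
#' @export
gfr_policy <- function(min_phase_ratio = 3, use_aic = TRUE,
                       bound_tol = 1e-6, weighting = c("none", "inv_c2")) {
  weighting <- match.arg(weighting)
  structure(list(min_phase_ratio = min_phase_ratio, use_aic = use_aic,
                 bound_tol = bound_tol, weighting = weighting),
            class = "crush_gfr_policy")
}

#' @export
print.crush_study_config <- function(x, ...) {
  cat("<crush_study_config>\n")
  cat("  groups:", paste(sprintf("%s=%d", names(x$group_sizes), x$group_sizes),
                         collapse = ", "), "\n")
  cat("  chemistry draws (h):", paste(x$chem_times_h, collapse = ", "), "\n")
  cat("  iohexol injections (h):", paste(x$iohexol_injection_times_h, collapse = ", "),
      "| dose", x$iohexol_dose_mg, "mg\n")
  cat("  K threshold:", x$k_threshold_mmol_l, "mmol/L | recovery fraction:",
      x$recovery_fraction, "| seed:", x$seed, "\n")
  invisible(x)
}

# resolve a per-group parameter for a group name
group_param <- function(param, group) {
  if (is.null(names(param))) return(param[[1]])
  unname(param[[group]])
}
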