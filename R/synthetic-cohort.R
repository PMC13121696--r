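#' Two-compartment iohexol macro-constants from micro-rates
#'
#' Converts the micro-rate parameterization (elimination `k10 = GFR/V1`,
#' inter-compartment rates `k12`, `k21`) of a two-compartment disposition
#' model into the macro-constants of the biexponential plasma decay
#' `C(t) = A exp(-alpha t) + B exp(-beta t)` after an ideal bolus.
#' With `k12 = k21 = 0` the model collapses to a monoexponential
#' (`A = dose/V1`, `alpha = k10`, `B = beta = 0`).
#'
#' @param gfr_ml_min Glomerular filtration rate (mL/min); iohexol is cleared
#'   solely by filtration, so plasma clearance equals GFR.
#' @param dose_mg Bolus iohexol mass (mg).
#' @param v_central_l Central compartment volume V1 (L).
#' @param k12_per_min,k21_per_min Inter-compartment micro-rates (1/min).
#' @return List with `A`, `alpha`, `B`, `beta` (concentrations in ug/mL
#'   because mg/L = ug/mL, rates in 1/min).
#' @export
iohexol_macro_constants <- function(gfr_ml_min, dose_mg, v_central_l,
                                    k12_per_min, k21_per_min) {
  assert_positive(gfr_ml_min, "gfr_ml_min")
  assert_positive(dose_mg, "dose_mg")
  assert_positive(v_central_l, "v_central_l")
  if (k12_per_min < 0 || k21_per_min < 0) abort("inter-compartment rates must be >= 0")
  k10 <- gfr_ml_min / (1000 * v_central_l)   # 1/min
  c0 <- dose_mg / v_central_l                # mg/L == ug/mL
  if (k12_per_min == 0 || k21_per_min == 0) {
    return(list(A = c0, alpha = k10 + k12_per_min, B = 0, beta = 0))
  }
  s <- k10 + k12_per_min + k21_per_min
  p <- k10 * k21_per_min
  disc <- sqrt(s^2 - 4 * p)
  alpha <- (s + disc) / 2
  beta <- (s - disc) / 2
  list(A = c0 * (alpha - k21_per_min) / (alpha - beta),
       alpha = alpha,
       B = c0 * (k21_per_min - beta) / (alpha - beta),
       beta = beta)
}

#' Simulate an iohexol plasma concentration-time series
#'
#' Forward-simulates the post-bolus plasma iohexol decay at the scheduled
#' sampling offsets under the two-compartment model, with multiplicative
#' lognormal measurement noise of the stated coefficient of variation
#' (noise factors are mean-one, so `noise_cv = 0` returns the noiseless
#' curve).
#'
#' @inheritParams iohexol_macro_constants
#' @param offsets_min Sampling times after injection (min).
#' @param noise_cv Assay coefficient of variation (>= 0).
#' @param seed Optional seed for the noise draws.
#' @return Tibble with `offset_min`, `concentration_ug_ml` and a `dose_mg`
#'   column, one row per sample.
#' @export
#' @examples
#' simulate_iohexol_series(gfr_ml_min = 80, dose_mg = 3235, noise_cv = 0)
simulate_iohexol_series <- function(gfr_ml_min, dose_mg,
                                    v_central_l = 3.5,
                                    k12_per_min = 0.05, k21_per_min = 0.02,
                                    offsets_min = c(15, 30, 90, 120, 180, 240, 300),
                                    noise_cv = 0, seed = NULL) {
  assert_that(noise_cv >= 0, "`noise_cv` must be >= 0")
  mac <- iohexol_macro_constants(gfr_ml_min, dose_mg, v_central_l,
                                 k12_per_min, k21_per_min)
  conc <- mac$A * exp(-mac$alpha * offsets_min) + mac$B * exp(-mac$beta * offsets_min)
  if (!is.null(seed)) set.seed(seed)
  conc <- conc * lognormal_factors(length(conc), noise_cv)
  tibble::tibble(offset_min = offsets_min,
                 concentration_ug_ml = conc,
                 dose_mg = dose_mg)
}

# true GFR trajectory (mL/min): baseline until impact, exponential decline to
# the injured level, then linear recovery from `recovery_start_h`, capped at
# baseline.  Vectorized over `t`.
gfr_trajectory <- function(t, base, drop, tau, rate, impact_time, recovery_start) {
  injured <- base * (1 - drop)
  decline <- injured + (base - injured) * exp(-pmax(0, t - impact_time) / tau)
  at_start <- injured + (base - injured) * exp(-(recovery_start - impact_time) / tau)
  recov <- pmin(base, at_start + rate * (t - recovery_start))
  out <- ifelse(t < impact_time, base, ifelse(t <= recovery_start, decline, recov))
  out
}

# saturating post-impact CK rise (IU/L), vectorized over t
ck_trajectory <- function(t, ck_base, plateau, tau, impact_time) {
  ck_base + plateau * (1 - exp(-pmax(0, t - impact_time) / tau))
}

# creatinine mass balance dC/dt = (G - 0.6 * GFR(t) * C) / (10 V)
# (C in mg/dL, G in mg/h, V in L, GFR in mL/min; 0.6 converts mL/min * mg/dL
# to mg/h).  RK4 on a fixed grid; columns of `gfr_fun(t)` may be vectors over
# animals, so the integration is vectorized across a cohort.
integrate_creatinine <- function(times_grid, gfr_mat, G, V, c0) {
  n_t <- length(times_grid)
  out <- matrix(NA_real_, n_t, length(c0))
  out[1, ] <- c0
  f <- function(gfr, C) (G - 0.6 * gfr * C) / (10 * V)
  for (j in seq_len(n_t - 1)) {
    h <- times_grid[j + 1] - times_grid[j]
    g0 <- gfr_mat[j, ]; g1 <- gfr_mat[j + 1, ]; gm <- (g0 + g1) / 2
    C <- out[j, ]
    k1 <- f(g0, C)
    k2 <- f(gm, C + h / 2 * k1)
    k3 <- f(gm, C + h / 2 * k2)
    k4 <- f(g1, C + h * k3)
    out[j + 1, ] <- C + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  out
}

#' Generate a seeded synthetic crush-syndrome cohort
#'
#' Builds a full synthetic cohort with the statistical structure the analysis
#' pipeline assumes: per-animal baseline GFR, a latent rapid-recovery status
#' drawn per group, a piecewise GFR trajectory (stable baseline, exponential
#' post-impact decline, linear recovery from 24 h), creatinine from a
#' one-compartment mass balance (so creatinine couples inversely to GFR),
#' saturating CK rise with potassium coupled to CK, protocolized hyperkalemia
#' interventions applied whenever a scheduled potassium draw strictly exceeds
#' the threshold (each dropping potassium persistently), urinary
#' myoglobin/porphyrin excretion with per-group multipliers, and biexponential
#' iohexol sampling around each injection.
#'
#' Randomness is fully reproducible: every animal draws from its own RNG
#' substream derived by stable hashing of its animal id, so identical
#' configurations give bit-identical cohorts and enlarging a group never
#' perturbs previously generated animals.
#'
#' @param study A [study_config()].
#' @param effects An [effect_config()].
#' @return An object of class `crush_cohort`: a list of tibbles `animals`,
#'   `chem`, `urine`, `iohexol`, `events`, and `truth` (hidden generating
#'   values for parameter-recovery testing), plus the two configs.
#' @export
#' @examples
#' cohort <- generate_cohort(study_config(seed = 1), effect_config())
#' cohort
generate_cohort <- function(study = study_config(), effects = effect_config()) {
  stopifnot(inherits(study, "crush_study_config"),
            inherits(effects, "crush_effect_config"))
  groups <- names(study$group_sizes)
  ids <- unlist(lapply(groups, function(g) {
    n <- study$group_sizes[[g]]
    if (n <= 0) character(0) else sprintf("%s_%02d", g, seq_len(n))
  }))
  id_group <- sub("_[0-9]+$", "", ids)
  n_animal <- length(ids)

  tt <- study$chem_times_h
  n_t <- length(tt)
  urine_times <- tt[tt >= 0]
  n_u <- length(urine_times)
  inj <- study$iohexol_injection_times_h
  off <- study$iohexol_sample_offsets_min
  n_io <- length(inj) * length(off)

  # --- per-animal randomness, one substream per animal -----------------------
  par <- vector("list", n_animal)
  for (i in seq_len(n_animal)) {
    g <- id_group[i]
    set.seed(substream_seed(study$seed, ids[i]))
    par[[i]] <- list(
      gfr_base = max(30, rnorm(1, effects$baseline_gfr_ml_min[["mean"]],
                               effects$baseline_gfr_ml_min[["sd"]])),
      recovered = runif(1) < group_param(effects$recovery_probability, g),
      cr_noise = lognormal_factors(n_t, effects$creatinine_noise_cv),
      k_noise = rnorm(n_t, 0, effects$k_noise_sd),
      ck_noise = lognormal_factors(n_t, effects$ck_noise_cv),
      mb_noise = lognormal_factors(n_t, effects$ck_noise_cv),
      bun_noise = lognormal_factors(n_t, 0.05),
      ca_noise = rnorm(n_t, 0, 0.01),
      be_noise = rnorm(n_t, 0, 0.5),
      uout_noise = lognormal_factors(n_u, effects$urine_noise_cv),
      ucr_noise = lognormal_factors(n_u, effects$urine_noise_cv),
      umb_noise = lognormal_factors(n_u, effects$urine_noise_cv),
      porph_noise = lognormal_factors(n_u, effects$porphyrin_noise_cv),
      io_noise = lognormal_factors(n_io, effects$iohexol_noise_cv)
    )
  }
  gfr_base <- vapply(par, `[[`, 0, "gfr_base")
  recovered <- vapply(par, `[[`, TRUE, "recovered")
  drop <- vapply(id_group, function(g) group_param(effects$injury_gfr_drop_fraction, g), 0)
  rate <- ifelse(recovered,
                 vapply(id_group, function(g) group_param(effects$recovery_rate_per_h, g), 0),
                 effects$nonrecovery_rate_per_h)
  rate[drop == 0] <- 0

  gfr_at <- function(t_vec) {
    vapply(seq_len(n_animal), function(i) {
      gfr_trajectory(t_vec, gfr_base[i], drop[i], effects$gfr_decline_tau_h,
                     rate[i], study$impact_time_h, effects$recovery_start_h)
    }, numeric(length(t_vec)))
  }

  # --- creatinine by mass balance on a fine grid ----------------------------
  grid <- seq(tt[1], tt[n_t], by = 0.25)
  if (grid[length(grid)] < tt[n_t]) grid <- c(grid, tt[n_t])
  grid <- sort(unique(c(grid, tt)))
  gfr_grid <- gfr_at(grid)                     # length(grid) x n_animal
  G <- effects$creatinine_production_rate_mg_h
  V <- effects$creatinine_volume_l
  cr_grid <- integrate_creatinine(grid, gfr_grid, G, V, G / (0.6 * gfr_base))
  cr_chem <- cr_grid[match(tt, grid), , drop = FALSE]  # n_t x n_animal, true values

  # --- assemble chemistry, events, urine, iohexol ---------------------------
  # per-animal columns are filled into matrices (time x animal) and flattened
  # into tibbles once, which keeps cohort generation fast enough for
  # many-cohort calibration studies
  ck_pl <- vapply(id_group, function(g) group_param(effects$ck_plateau_iu_l, g), 0)
  event_list <- vector("list", n_animal)
  truth_io <- matrix(NA_real_, n_animal, length(inj))
  k_obs_m <- cr_m <- bun_m <- ca_m <- ck_m <- mb_m <- be_m <- matrix(NA_real_, n_t, n_animal)
  uout_m <- umb_m <- ucr_m <- uporph_m <- matrix(NA_real_, n_u, n_animal)
  io_m <- matrix(NA_real_, n_io, n_animal)
  u_idx <- match(urine_times, tt)

  for (i in seq_len(n_animal)) {
    g <- id_group[i]
    p <- par[[i]]
    ck_true <- ck_trajectory(tt, effects$ck_baseline_iu_l, ck_pl[i],
                             effects$ck_tau_h, study$impact_time_h)
    cr_true <- cr_chem[, i]
    cil_late <- (g == "cilastatin") & (tt >= 12)
    mb_true <- effects$plasma_mb_per_ck * ck_true * ifelse(cil_late, 0.45, 1)

    # potassium with sequential protocolized interventions at scheduled draws
    k_model <- effects$k_baseline_mmol_l + effects$k_per_ck *
      ck_trajectory(tt, 0, ck_pl[i], effects$ck_tau_h, study$impact_time_h)
    drops <- 0
    k_obs <- numeric(n_t)
    ev_t <- numeric(0); ev_k <- numeric(0)
    for (j in seq_len(n_t)) {
      k_obs[j] <- max(0, k_model[j] - drops + p$k_noise[j])
      if (k_obs[j] > study$k_threshold_mmol_l) {
        ev_t <- c(ev_t, tt[j]); ev_k <- c(ev_k, k_obs[j])
        drops <- drops + effects$intervention_k_drop_mmol_l
      }
    }
    if (length(ev_t)) {
      event_list[[i]] <- list(animal_id = rep(ids[i], length(ev_t)),
                              time_h = ev_t, trigger_potassium_mmol_l = ev_k)
    }

    dip <- if (g == "vehicle") 1 else if (g == "cilastatin") 0.4 else 0
    k_obs_m[, i] <- k_obs
    cr_m[, i] <- cr_true * p$cr_noise
    bun_m[, i] <- 12 * cr_true * p$bun_noise
    ca_m[, i] <- pmax(0, 1.30 - dip * 0.07 * exp(-((tt - 18)^2) / 128) + p$ca_noise)
    ck_m[, i] <- ck_true * p$ck_noise
    mb_m[, i] <- mb_true * p$mb_noise
    be_m[, i] <- -(drop[i] > 0) * 4 * (1 - exp(-pmax(0, tt) / 12)) +
      2 * (g == "cilastatin") * (tt >= 12) + p$be_noise

    # urine panel at scheduled times >= 0
    u_cr <- 50 * p$ucr_noise
    fe_mult <- group_param(effects$myoglobin_fe_multiplier, g)
    uout_m[, i] <- (0.5 + 2.5 * exp(-pmax(0, urine_times) / 6)) *
      ifelse(g == "cilastatin" & urine_times > 0 & urine_times <= 2, 1.67, 1) *
      p$uout_noise
    umb_m[, i] <- effects$fe_mb_base * fe_mult * mb_true[u_idx] *
      u_cr / pmax(cr_true[u_idx], 1e-6) * p$umb_noise
    ucr_m[, i] <- u_cr
    uporph_m[, i] <- effects$porphyrin_cr_ratio * fe_mult * u_cr * p$porph_noise

    # iohexol series per injection at the true GFR prevailing at injection
    gfr_inj <- gfr_trajectory(inj, gfr_base[i], drop[i], effects$gfr_decline_tau_h,
                              rate[i], study$impact_time_h, effects$recovery_start_h)
    truth_io[i, ] <- gfr_inj
    conc <- unlist(lapply(seq_along(inj), function(k) {
      mac <- iohexol_macro_constants(gfr_inj[k], study$iohexol_dose_mg,
                                     effects$iohexol_v_central_l,
                                     effects$iohexol_k12_per_min,
                                     effects$iohexol_k21_per_min)
      mac$A * exp(-mac$alpha * off) + mac$B * exp(-mac$beta * off)
    }))
    io_m[, i] <- conc * p$io_noise
  }

  gfr_2448 <- gfr_at(c(effects$recovery_start_h, max(tt)))
  truth <- tibble::tibble(
    animal_id = ids, group = id_group,
    gfr_base_ml_min = gfr_base, recovered = recovered,
    injury_drop_fraction = drop, recovery_rate_ml_min_h = rate
  )
  for (k in seq_along(inj)) truth[[sprintf("gfr_true_inj%d", k)]] <- truth_io[, k]
  truth$gfr_true_24h <- gfr_2448[1, ]
  truth$gfr_true_48h <- gfr_2448[2, ]

  event_list <- event_list[!vapply(event_list, is.null, TRUE)]
  events <- tibble::tibble(
    animal_id = unlist(lapply(event_list, `[[`, "animal_id")) %||% character(),
    time_h = unlist(lapply(event_list, `[[`, "time_h")) %||% numeric(),
    trigger_potassium_mmol_l =
      unlist(lapply(event_list, `[[`, "trigger_potassium_mmol_l")) %||% numeric())
  chem <- tibble::tibble(
    animal_id = rep(ids, each = n_t), time_h = rep(tt, n_animal),
    potassium_mmol_l = as.vector(k_obs_m),
    creatinine_mg_dl = as.vector(cr_m),
    bun_mg_dl = as.vector(bun_m),
    ionized_ca_mmol_l = as.vector(ca_m),
    ck_iu_l = as.vector(ck_m),
    plasma_myoglobin_ng_ml = as.vector(mb_m),
    base_excess = as.vector(be_m))
  urine <- tibble::tibble(
    animal_id = rep(ids, each = n_u), time_h = rep(urine_times, n_animal),
    output_ml_kg_h = as.vector(uout_m),
    urine_myoglobin_ng_ml = as.vector(umb_m),
    urine_creatinine_mg_dl = as.vector(ucr_m),
    urine_porphyrin_ug = as.vector(uporph_m))
  iohexol <- tibble::tibble(
    animal_id = rep(ids, each = n_io),
    injection_time_h = rep(rep(inj, each = length(off)), n_animal),
    offset_min = rep(off, times = length(inj) * n_animal),
    concentration_ug_ml = as.vector(io_m),
    dose_mg = study$iohexol_dose_mg)
  structure(list(
    animals = tibble::tibble(animal_id = ids, group = id_group,
                             weight_kg = study$animal_weight_kg,
                             excluded = FALSE, exclusion_reason = NA_character_),
    chem = chem,
    urine = urine,
    iohexol = iohexol,
    events = events,
    truth = truth,
    study = study, effects = effects
  ), class = "crush_cohort")
}

#' @export
print.crush_cohort <- function(x, ...) {
  cat("<crush_cohort>", nrow(x$animals), "animals (",
      paste(sprintf("%s=%d", names(x$study$group_sizes), x$study$group_sizes),
            collapse = ", "), ")\n")
  cat("  chemistry rows:", nrow(x$chem), "| urine rows:", nrow(x$urine),
      "| iohexol samples:", nrow(x$iohexol),
      "| hyperkalemia events:", nrow(x$events), "\n")
  cat("  seed:", x$study$seed, "\n")
  invisible(x)
}

#' Write a cohort to plain-text CSV files
#'
#' Chemistry and urine panels are written in long format (one row per
#' `animal_id`, `time_h`, `analyte`, `value`); iohexol samples, events,
#' animals and hidden truth as typed tables; the study configuration as JSON.
#' Serialization uses shortest-round-trip formatting of doubles, so
#' `read_cohort_csv()` recovers the cohort exactly.
#'
#' @param cohort A `crush_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_cohort_csv <- function(cohort, dir) {
  stopifnot(inherits(cohort, "crush_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- function(tbl) {
    tidyr::pivot_longer(tbl, -c("animal_id", "time_h"),
                        names_to = "analyte", values_to = "value")
  }
  paths <- c(
    animals = file.path(dir, "animals.csv"),
    chem = file.path(dir, "chem.csv"),
    urine = file.path(dir, "urine.csv"),
    iohexol = file.path(dir, "iohexol.csv"),
    events = file.path(dir, "events.csv"),
    truth = file.path(dir, "truth.csv"),
    config = file.path(dir, "study_config.json")
  )
  readr::write_csv(cohort$animals, paths[["animals"]])
  readr::write_csv(long(cohort$chem), paths[["chem"]])
  readr::write_csv(long(cohort$urine), paths[["urine"]])
  readr::write_csv(cohort$iohexol, paths[["iohexol"]])
  readr::write_csv(cohort$events, paths[["events"]])
  readr::write_csv(cohort$truth, paths[["truth"]])
  cfg <- unclass(cohort$study)
  cfg$group_sizes <- as.list(cfg$group_sizes)  # keep names in JSON
  jsonlite::write_json(cfg, paths[["config"]], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a cohort previously written by [write_cohort_csv()]
#'
#' @param dir Directory holding the CSV bundle.
#' @return A `crush_cohort` (the `effects` slot is not serialized and is
#'   restored as `NULL`).
#' @export
read_cohort_csv <- function(dir) {
  spec_cols <- function(path, required) {
    x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    require_columns(x, required, basename(path))
    x
  }
  wide <- function(tbl) {
    tidyr::pivot_wider(tbl, names_from = "analyte", values_from = "value")
  }
  cfg <- jsonlite::read_json(file.path(dir, "study_config.json"), simplifyVector = TRUE)
  study <- study_config(group_sizes = unlist(cfg$group_sizes),
                        animal_weight_kg = cfg$animal_weight_kg,
                        chem_times_h = cfg$chem_times_h,
                        iohexol_injection_times_h = cfg$iohexol_injection_times_h,
                        iohexol_sample_offsets_min = cfg$iohexol_sample_offsets_min,
                        iohexol_dose_mg = cfg$iohexol_dose_mg,
                        k_threshold_mmol_l = cfg$k_threshold_mmol_l,
                        recovery_fraction = cfg$recovery_fraction,
                        impact_time_h = cfg$impact_time_h,
                        seed = cfg$seed)
  animals <- spec_cols(file.path(dir, "animals.csv"),
                       c("animal_id", "group", "weight_kg", "excluded"))
  animals$exclusion_reason <- as.character(animals$exclusion_reason)
  structure(list(
    animals = animals,
    chem = wide(spec_cols(file.path(dir, "chem.csv"),
                          c("animal_id", "time_h", "analyte", "value"))),
    urine = wide(spec_cols(file.path(dir, "urine.csv"),
                           c("animal_id", "time_h", "analyte", "value"))),
    iohexol = spec_cols(file.path(dir, "iohexol.csv"),
                        c("animal_id", "injection_time_h", "offset_min",
                          "concentration_ug_ml", "dose_mg")),
    events = spec_cols(file.path(dir, "events.csv"),
                       c("animal_id", "time_h", "trigger_potassium_mmol_l")),
    truth = readr::read_csv(file.path(dir, "truth.csv"),
                            show_col_types = FALSE, progress = FALSE),
    study = study, effects = NULL
  ), class = "crush_cohort")
}
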