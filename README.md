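# crushkit

Crush syndrome — the hyperkalemia, acidosis, hypocalcemia and acute kidney
injury (AKI) that follow traumatic skeletal-muscle destruction — is a major
cause of death after earthquakes, blasts and prolonged immobility, and has
no specific treatment. Efficacy studies in large-animal (porcine) models
assess candidate drugs with repeated measured GFR, serial blood/urine
chemistry under protocolized critical care, and recovery classification.
crushkit packages that quantitative analysis as a tested, reusable R
pipeline for biostatisticians and translational researchers working on
rhabdomyolysis-induced AKI:

* **Measured GFR by iohexol clearance** (`estimate_gfr()`, `fit_gfr()`):
  nonlinear least-squares fit of the biexponential two-compartment decay
  C(t) = A·e^(−αt) + B·e^(−βt) initialized by curve stripping, a
  one-compartment fallback under an explicit poor-fit policy, and
  GFR = dose / AUC with AUC = A/α + B/β.
* **Renal outcomes** (`classify_rapid_recovery()`, `apply_exclusions()`):
  rapid recovery as 48 h creatinine strictly < 70% of maximal creatinine;
  a priori CK-non-response and baseline-outlier exclusions; GFR recovery
  slope; fractional excretion of myoglobin; 48 h creatinine-normalized
  porphyrin excretion.
* **Hyperkalemia events** (`detect_interventions()`, `km_estimate()`,
  `logrank_test()`): protocolized interventions for potassium > 5.0 mmol/L,
  with Kaplan–Meier and log-rank time-to-first-event analysis implemented
  from first principles.
* **Summary statistics** (`welch_t()`, `fisher_exact_2x2()`,
  `chi_square_2x2()`, `sidak_adjust()`, `median_iqr()`): Welch tests
  directly from printed summary statistics, exact and asymptotic 2×2
  inference, Šidák multiplicity adjustment.
* **Clinical-trial power** (`power_curve()`, `simulate_trial()`): Monte
  Carlo power for a two-arm binary rapid-recovery outcome with an analytic
  two-proportion oracle.
* **Synthetic cohorts** (`generate_cohort()`): a seeded generator with the
  statistical structure the analysis assumes (biexponential iohexol
  kinetics, creatinine mass balance coupled to a piecewise GFR trajectory,
  CK-coupled potassium with protocolized intervention drops), so the whole
  pipeline runs and is tested without animal data.

Everything is tibble-in/tibble-out and pipe-friendly, with `tidy()`,
`glance()` and `autoplot()` methods for fitted objects, and
`run_pipeline()` to orchestrate an end-to-end run with a reproducible
manifest. A thin command-line wrapper ships in `inst/cli/crushkit.R`.

## Worked example

```r
library(crushkit)

cohort <- generate_cohort(study_config(seed = 1), effect_config())
cohort
#> <crush_cohort> 36 animals ( no_impact=6, vehicle=9, cilastatin=21 )
#>   chemistry rows: 288 | urine rows: 252 | iohexol samples: 756 | hyperkalemia events: 160
#>   seed: 1

fit_gfr(cohort$iohexol) |> head(3)
#> # A tibble: 3 x 13
#>   animal_id     injection_time_h model_order ... gfr_ml_min fallback_used
#> 1 cilastatin_01                1           2            91.0 FALSE
#> 2 cilastatin_01               19           2            43.9 FALSE
#> 3 cilastatin_01               43           2            48.3 FALSE
```

The three GFR values per animal trace the injury: ~91 mL/min shortly after
impact (1 h), a nadir near 44 mL/min at 19 h, and partial recovery by the
43 h injection. Recovery classification and group-level inference:

```r
outcomes <- assess_recovery(apply_exclusions(cohort))
(tab <- recovery_table(outcomes))
#>            recovered not_recovered
#> cilastatin         9            10
#> vehicle            2             6

fisher_exact_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
#> <Fisher exact test (two-sided, probability-mass rule)>
#>   p = 0.4048
```

(One simulated 36-animal cohort is underpowered, which is the point of the
power analysis below. On the study-scale reconstructed table, 12/21 treated
vs 1/9 control recoverers, `fisher_exact_2x2(12, 9, 1, 8)` gives
p = 0.0417.) A Welch test straight from printed summaries — 48 h porphyrin
excretion 52.6 ± 31.3 (n = 9) vs 110.4 ± 96.4 (n = 21):

```r
welch_t(52.6, 31.3, 9, 110.4, 96.4, 21)
#> <Welch two-sample t-test (summary statistics)>
#>   statistic = 2.4615, df = 26.97, p = 0.02052
```

Monte Carlo power for a future two-arm trial using the observed recovery
proportions, 500 trials per total sample size 20–200 at α = 0.01:

```r
pc <- power_curve(n_grid = seq(20, 200, 2), reps_per_n = 500, seed = 7)
glance(pc)
#> # A tibble: 1 x 8
#>   minimal_n_total minimal_n_per_group target_reached p_treat p_ctrl sig_level ...
#> 1              56                  28 TRUE             0.571  0.111      0.01
autoplot(pc)
```

With these proportions the fitted power crosses 90% at 56 total subjects —
comfortably inside a 124-patient design — so 62 per group is a conservative
enrollment target for this effect size.

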