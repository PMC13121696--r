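# shared fixtures built in code

# noiseless biexponential series from macro-constants
biexp_series <- function(A, alpha, B, beta,
                         t = c(15, 30, 90, 120, 180, 240, 300)) {
  list(t = t, c = A * exp(-alpha * t) + B * exp(-beta * t))
}

# small study config for fast cohort-based tests
small_study <- function(seed = 1, ...) {
  study_config(group_sizes = c(no_impact = 2, vehicle = 3, cilastatin = 4),
               seed = seed, ...)
}

# a worked right-censored survival set used in several event-analysis tests:
# censored at 2, events at 3, 4, 4, censored at 7
worked_survival <- function() {
  tibble::tibble(time_h = c(2, 3, 4, 4, 7), event = c(0, 1, 1, 1, 0))
}
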