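# internal helpers: validation, seeding, numerics

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg)
  invisible(TRUE)
}

assert_prob <- function(x, field) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must contain probabilities in [0, 1]", field))
  }
  invisible(TRUE)
}

assert_positive <- function(x, field) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("`%s` must be positive and finite", field))
  }
  invisible(TRUE)
}

assert_increasing <- function(x, field) {
  if (length(x) > 1 && any(diff(x) <= 0)) {
    abort(sprintf("`%s` must be strictly increasing", field))
  }
  invisible(TRUE)
}

# Stable 31-base polynomial hash of a string, mod 2^31 - 1.  Used to derive
# per-animal RNG substreams so that adding animals to a cohort never perturbs
# the draws of existing ones.
hash_string <- function(s) {
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  h
}

substream_seed <- function(master_seed, id) {
  as.integer((hash_string(id) * 69069 + as.numeric(master_seed)) %% 2147483647)
}

# trapezoid rule over (x, y)
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) abort("trapezoid integration needs at least 2 points")
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}

# lognormal sdlog for a given coefficient of variation
cv_to_sdlog <- function(cv) sqrt(log(1 + cv^2))

# multiplicative lognormal noise factors with mean-one parameterization
lognormal_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- cv_to_sdlog(cv)
  exp(rnorm(n, -sdlog^2 / 2, sdlog))
}

require_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing)) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}
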