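# Independent reference implementations used as oracles. These deliberately
# share no code with the package internals: the density uses only the
# large-time eigenfunction expansion with a fixed large number of terms, and
# the summary statistics are direct textbook-formula transcriptions.

# first-passage density at the LOWER boundary (drift v towards upper),
# large-time series only, valid away from tau ~ 0
ref_fpt_lower <- function(tau, v, a, w, K = 2000) {
  u <- tau / a^2
  k <- seq_len(K)
  f0 <- pi * sum(k * exp(-k^2 * pi^2 * u / 2) * sin(k * pi * w))
  f0 / a^2 * exp(-v * a * w - v^2 * tau / 2)
}

ref_fpt <- function(rt, upper, v, a, w, t0) {
  tau <- rt - t0
  if (tau <= 0) return(0)
  if (upper) ref_fpt_lower(tau, -v, a, 1 - w) else ref_fpt_lower(tau, v, a, w)
}

ref_pearson <- function(x, y) {
  n <- length(x)
  num <- sum((x - mean(x)) * (y - mean(y)))
  num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

ref_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  mean(d) / (sd(d) / sqrt(n))
}

# Gelman-Rubin for one parameter from a list of equal-length draw vectors
ref_psrf <- function(chains) {
  m <- length(chains)
  n <- length(chains[[1]])
  means <- vapply(chains, mean, 0)
  W <- mean(vapply(chains, var, 0))
  B <- n * var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

# small synthetic study used by several fitting tests
tiny_study <- function(n_subjects = 5, n_trials = 30, seed = 42, ...) {
  generate_choice_study(
    population_config("study1", n_subjects = n_subjects,
                      n_trials = n_trials, ...), seed = seed)
}
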