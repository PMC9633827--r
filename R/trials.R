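#' Net subjective value of the harmful option for a harm-averse agent
#'
#' A simulated agent with harm aversion `kappa` values the high (more money,
#' more shocks) option relative to the low option as
#' \eqn{(1-\kappa)\,\Delta m - \kappa\,\Delta s}. The value is zero exactly at
#' the agent's indifference point; `kappa = 0` ignores shocks entirely and
#' `kappa = 1` ignores money entirely.
#'
#' @param kappa harm-aversion coefficient in \[0, 1\].
#' @param delta_m money difference between the options (GBP, > 0).
#' @param delta_s shock difference between the options (integer >= 1).
#' @return Signed net value of the high option (unitless).
#' @examples
#' indifference_gap(0.5, 3, 3)   # 0: symmetric indifference
#' indifference_gap(0.3, 2, 4)   # 0.7*2 - 0.3*4 = 0.2
#' @export
indifference_gap <- function(kappa, delta_m, delta_s) {
  if (any(kappa < 0 | kappa > 1)) stop("kappa must lie in [0, 1]")
  if (any(delta_m <= 0)) stop("delta_m must be positive")
  if (any(delta_s < 1)) stop("delta_s must be >= 1")
  (1 - kappa) * delta_m - kappa * delta_s
}

#' Select the candidate attribute pair closest to an agent's indifference
#'
#' Given candidate `(delta_s, delta_m)` pairs, returns the one minimising the
#' absolute [indifference_gap()] for the agent; ties are broken by the lowest
#' candidate index so that selection is reproducible.
#'
#' @param kappa harm-aversion coefficient in \[0, 1\].
#' @param candidates two-column matrix or data frame, columns `delta_s`,
#'   `delta_m` (in that order).
#' @return Named numeric vector `c(delta_s, delta_m)`.
#' @export
select_candidate_pair <- function(kappa, candidates) {
  candidates <- as.matrix(candidates)
  if (nrow(candidates) == 0L) stop("candidate list is empty")
  gap <- abs(indifference_gap(kappa, candidates[, 2L], candidates[, 1L]))
  i <- which.min(gap) # which.min returns the first minimum: lowest index wins
  c(delta_s = unname(candidates[i, 1L]), delta_m = unname(candidates[i, 2L]))
}

#' Generate an indifference-point-matched trial set
#'
#' Builds `n_trials` choice trials, one per harm-aversion coefficient on an
#' equidistant grid over \[0, 1\] (endpoints included). For each kappa, 1000
#' candidate pairs are drawn (`delta_s` uniform integer 1-20, `delta_m`
#' uniform on a 10-pence grid in \[0.1, 19.9\]), the pair closest to the
#' agent's indifference point is selected, and the low option's shocks and
#' money are then drawn uniformly subject to the variant's bounds. The high
#' option adds the selected differences. Sides are counterbalanced by
#' alternating which option appears on the left.
#'
#' Variant bounds: `study1` allows 0-20 shocks and GBP 0-20 per option;
#' `study2` (used for the judged decisions in the blame task) requires at
#' least 1 shock and GBP 0.10 per option, which additionally rules out
#' `delta_s = 20`.
#'
#' @param n_trials number of trials (and of kappa grid points).
#' @param variant `"study1"` or `"study2"` option bounds.
#' @param seed integer seed; the same seed always yields the same set.
#' @param n_candidates candidate pairs drawn per kappa (default 1000).
#' @return Data frame of class `moral_trials` with columns `trial_id`,
#'   `kappa`, `s_low`, `m_low`, `s_high`, `m_high`, `delta_s`, `delta_m`,
#'   `high_on_left`.
#' @examples
#' tr <- generate_trial_set(42, variant = "study2", seed = 7)
#' check_attribute_independence(tr)
#' @export
generate_trial_set <- function(n_trials, variant = c("study1", "study2"),
                               seed = NULL, n_candidates = 1000L) {
  variant <- match.arg(variant)
  if (!.is_count(n_trials)) stop("n_trials must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  s_min <- if (variant == "study2") 1L else 0L
  m_min <- if (variant == "study2") 0.1 else 0
  kappa <- if (n_trials == 1L) 0.5 else seq(0, 1, length.out = n_trials)
  out <- data.frame(trial_id = seq_len(n_trials), kappa = kappa,
                    s_low = NA_integer_, m_low = NA_real_,
                    s_high = NA_integer_, m_high = NA_real_,
                    delta_s = NA_integer_, delta_m = NA_real_,
                    high_on_left = rep_len(c(TRUE, FALSE), n_trials))
  for (i in seq_len(n_trials)) {
    cds <- sample.int(20L, n_candidates, replace = TRUE)
    cdm <- round(runif(n_candidates, 0.1, 19.9) / 0.1) * 0.1
    # keep only pairs for which a feasible low option exists
    ok <- (cds <= 20L - s_min) & (cdm <= 20 - m_min + 1e-9)
    cds <- cds[ok]; cdm <- cdm[ok]
    sel <- select_candidate_pair(kappa[i], cbind(cds, cdm))
    ds <- as.integer(sel[["delta_s"]]); dm <- sel[["delta_m"]]
    s_low <- sample(seq.int(s_min, 20L - ds), 1L)
    m_grid <- seq(m_min, 20 - dm + 1e-9, by = 0.1)
    m_low <- round(m_grid[sample.int(length(m_grid), 1L)], 1)
    out$s_low[i] <- s_low
    out$m_low[i] <- m_low
    out$s_high[i] <- s_low + ds
    out$m_high[i] <- round(m_low + dm, 1)
    out$delta_s[i] <- ds
    out$delta_m[i] <- round(dm, 1)
  }
  class(out) <- c("moral_trials", "data.frame")
  out
}

#' Correlation between money and shock differences across trials
#'
#' The trial generator is meant to decorrelate `delta_m` and `delta_s` so that
#' drift weights on the two attributes are separately identifiable; this
#' reports the Pearson correlation with its two-sided p-value.
#'
#' @param trials data frame with `delta_m` and `delta_s` columns.
#' @return List with elements `r` and `p_value`.
#' @export
check_attribute_independence <- function(trials) {
  if (nrow(trials) < 3L) stop("need at least 3 trials")
  if (var(trials$delta_m) == 0 || var(trials$delta_s) == 0)
    stop("correlation undefined: an attribute has zero variance")
  ct <- cor.test(trials$delta_m, trials$delta_s)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}

# invariant checks shared by the generator tests and table readers
.validate_trials <- function(trials, variant = "study1") {
  s_min <- if (variant == "study2") 1L else 0L
  m_min <- if (variant == "study2") 0.1 else 0
  with(trials, all(
    s_low >= s_min, s_high <= 20, m_low >= m_min - 1e-9, m_high <= 20 + 1e-9,
    delta_s >= 1, delta_s <= 20, delta_m >= 0.1 - 1e-9, delta_m <= 19.9 + 1e-9,
    abs(s_high - s_low - delta_s) < 1e-9,
    abs(m_high - m_low - delta_m) < 1e-6))
}
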