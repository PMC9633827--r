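#' Drift-diffusion parameters for a single decision maker
#'
#' Container for the subject-level parameters of the multi-attribute DDM. The
#' diffusion coefficient is fixed at 1 (the usual scale convention: drift
#' weights are expressed in diffusion-noise units). The starting point is
#' stored relative to the boundary separation, `z` in (0, 1), with 0.5 the
#' unbiased midpoint; the absolute start is `z * a`. The upper boundary codes
#' the option with more shocks and more money ("high"/harmful response).
#'
#' `beta_m` and `beta_s` may be single numbers, or vectors named by condition
#' (`"dirty"`/`"clean"`, `"profit"`/`"charity"`, or combined
#' `"dirty_profit"`-style cells) for condition-specific drift weights; `z`
#' may likewise be named by source.
#'
#' @param a boundary separation (> 0, evidence units).
#' @param t0 non-decision time (seconds, >= 0).
#' @param beta_m drift weight per GBP of money difference.
#' @param beta_s drift weight per shock of shock difference.
#' @param z relative starting point in (0, 1); default 0.5 (unbiased).
#' @return Object of class `ddm_params`.
#' @examples
#' p <- ddm_params(a = 1.8, t0 = 0.4, beta_m = 0.35, beta_s = -0.12)
#' drift_rate(p, delta_m = 2, delta_s = 4)
#' @export
ddm_params <- function(a, t0, beta_m, beta_s, z = 0.5) {
  if (!all(a > 0)) stop("boundary separation a must be > 0")
  if (!all(t0 >= 0)) stop("non-decision time t0 must be >= 0")
  if (!all(z > 0 & z < 1)) stop("relative starting point z must lie in (0, 1)")
  structure(list(a = a, t0 = t0, beta_m = beta_m, beta_s = beta_s, z = z,
                 sigma = 1), class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("DDM parameters (sigma = 1):\n")
  cat("  a =", x$a, "  t0 =", x$t0, "s  z =", x$z, "\n")
  cat("  beta_m:", paste(format(x$beta_m), collapse = " "), "\n")
  cat("  beta_s:", paste(format(x$beta_s), collapse = " "), "\n")
  invisible(x)
}

# map a (possibly condition-named) weight onto records
.resolve_weight <- function(beta, records, what = "weight") {
  if (length(beta) == 1L && is.null(names(beta)))
    return(rep(unname(beta), nrow(records)))
  nm <- names(beta)
  if (is.null(nm)) stop("multiple ", what, " values need condition names")
  keys <- list()
  if (all(c("source", "destination") %in% names(records)))
    keys$cell <- paste(records$source, records$destination, sep = "_")
  if ("source" %in% names(records)) keys$source <- records$source
  if ("destination" %in% names(records)) keys$destination <- records$destination
  for (k in keys) if (all(unique(k) %in% nm)) return(unname(beta[k]))
  stop("cannot match ", what, " names (", paste(nm, collapse = ", "),
       ") to the records' condition labels")
}

#' Drift rate from trial attributes
#'
#' The mean evidence-accumulation rate towards the high (more money, more
#' shocks) option is linear in the attribute differences:
#' \eqn{v = \beta_m \Delta m + \beta_s \Delta s}.
#'
#' @param params a [ddm_params()] object.
#' @param delta_m money difference (GBP); vectorised.
#' @param delta_s shock difference; vectorised.
#' @param records optional data frame with condition columns, used to resolve
#'   condition-named weights.
#' @return Drift rate(s), evidence units per second.
#' @export
drift_rate <- function(params, delta_m, delta_s, records = NULL) {
  if (is.null(records))
    records <- data.frame(.row = seq_along(delta_m))
  bm <- .resolve_weight(params$beta_m, records, "beta_m")
  bs <- .resolve_weight(params$beta_s, records, "beta_s")
  bm * delta_m + bs * delta_s
}

#' Probability of hitting the upper (harmful) boundary
#'
#' Closed-form absorption probability of the diffusion at the upper boundary,
#' \eqn{p = (1 - e^{-2 v z a}) / (1 - e^{-2 v a})} for \eqn{v \neq 0} and
#' \eqn{p = z} at \eqn{v = 0} (computed with `expm1` so the two branches join
#' continuously).
#'
#' @param params a [ddm_params()] object (uses `a` and `z`).
#' @param v drift rate(s).
#' @return Probability in \[0, 1\], vectorised over `v`.
#' @export
choice_probability <- function(params, v) {
  a <- params$a
  z <- params$z
  x <- 2 * v * a
  p <- ifelse(abs(x) < 1e-12, z, expm1(-x * z) / expm1(-x))
  pmin(pmax(p, 0), 1)
}

#' First-passage-time density of the observed response
#'
#' Density (per second) of responding at the given boundary at time `t`,
#' where `t` includes the non-decision time: the decision process runs for
#' `t - t0`. Returns 0 for `t <= t0`. Computed with the dual small-time /
#' large-time series expansions of the Wiener first-passage distribution,
#' automatically choosing the faster-converging branch with truncation error
#' below 1e-10. The densities of the two boundaries together integrate to 1
#' over `t` in `(t0, Inf)`.
#'
#' @param t response time(s), seconds.
#' @param boundary `"upper"` (high/harmful response) or `"lower"`.
#' @param params a [ddm_params()] object.
#' @param v drift rate, scalar or one value per `t`.
#' @param log return the log density.
#' @return Density value(s).
#' @export
ddm_fpt_density <- function(t, boundary = c("upper", "lower"), params, v,
                            log = FALSE) {
  boundary <- match.arg(boundary)
  v <- rep_len(v, length(t))
  up <- as.integer(rep_len(boundary == "upper", length(t)))
  ll <- wiener_logdens_cpp(t, up, v, params$a, params$z, params$t0)
  ll[t <= params$t0] <- -Inf
  if (log) ll else exp(ll)
}

#' Log-likelihood of observed choices and response times
#'
#' Sum over records of the log first-passage density at the observed boundary
#' and RT, with the drift recomputed per trial from its `delta_m`, `delta_s`
#' and (for condition-named weights) its condition labels. Records with
#' `rt_seconds <= t0` contribute `-Inf`; their count is reported in the
#' `"n_invalid"` attribute rather than being dropped.
#'
#' @param params a [ddm_params()] object; weights may be condition-named.
#' @param records data frame with columns `response` (`"high"`/`"low"`),
#'   `rt_seconds`, `delta_m`, `delta_s`, and condition columns as needed.
#' @param trials optional trial table; if `records` lacks `delta_m`/`delta_s`
#'   they are merged in by `trial_id`.
#' @return Log-likelihood (nats) with attribute `n_invalid`.
#' @export
ddm_loglik <- function(params, records, trials = NULL) {
  if (!is.null(trials) && !all(c("delta_m", "delta_s") %in% names(records))) {
    idx <- match(records$trial_id, trials$trial_id)
    records$delta_m <- trials$delta_m[idx]
    records$delta_s <- trials$delta_s[idx]
  }
  v <- drift_rate(params, records$delta_m, records$delta_s, records)
  z <- .resolve_weight(params$z, records, "z")
  up <- as.integer(records$response == "high")
  ll <- numeric(nrow(records))
  for (zz in unique(z)) { # density is scalar in z; group records by cell
    i <- which(z == zz)
    ll[i] <- wiener_logdens_cpp(records$rt_seconds[i], up[i], v[i],
                                params$a, zz, params$t0)
  }
  bad <- records$rt_seconds <= params$t0
  ll[bad] <- -Inf
  structure(sum(ll), n_invalid = sum(bad))
}

#' Simulate decisions from the drift-diffusion process
#'
#' Draws one response (boundary and RT) per trial row by simulating the
#' diffusion path. Endpoint increments of the constant-drift process are
#' exactly Gaussian, and within-step boundary crossings are detected by a
#' Brownian-bridge test, so choice frequencies are unbiased at any step size;
#' `dt` only sets the resolution of the recorded crossing time. Trajectories
#' whose total RT would exceed the response window are redrawn, mirroring a
#' task deadline with re-presentation of missed trials.
#'
#' @param params a [ddm_params()] object (weights may be condition-named).
#' @param trials data frame with `delta_m`, `delta_s` (plus condition columns
#'   for named weights).
#' @param dt simulation step, seconds (default 0.001).
#' @param window response window, seconds (default 6; `Inf` disables).
#' @param seed optional seed.
#' @return Data frame with columns `response` (`"high"`/`"low"`) and
#'   `rt_seconds` (always `> t0`).
#' @export
simulate_ddm_trials <- function(params, trials, dt = 0.001, window = 6,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trials)
  v <- drift_rate(params, trials$delta_m, trials$delta_s, trials)
  z <- .resolve_weight(params$z, trials, "z")
  s <- sim_dataset_cpp(v, rep(params$a, n), z, rep(params$t0, n), dt, window)
  data.frame(response = ifelse(s$upper == 1, "high", "low"),
             rt_seconds = s$rt)
}

#' Simulate first-passage times for a fixed drift
#'
#' Low-level simulator: `n` independent paths with a single drift rate.
#'
#' @inheritParams simulate_ddm_trials
#' @param n number of paths.
#' @param v drift rate.
#' @return Data frame with `response` and `rt_seconds`.
#' @export
simulate_ddm_paths <- function(n, params, v, dt = 0.001, window = 6,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  s <- simulate_paths_cpp(as.integer(n), v, params$a, params$z, params$t0,
                          dt, window)
  data.frame(response = ifelse(s$upper == 1, "high", "low"),
             rt_seconds = s$rt)
}
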