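#' Deviance information criterion of a hierarchical DDM fit
#'
#' DIC combines the posterior mean deviance \eqn{\bar D} (lack of fit) with
#' the effective number of parameters \eqn{p_D = \bar D - D(\bar\theta)},
#' where \eqn{D(\theta) = -2 \log L(\theta)} and \eqn{\bar\theta} is the
#' posterior mean of the subject-level parameters on their sampling scale:
#' \eqn{DIC = \bar D + p_D}. Lower is better.
#'
#' @param fit a [ddm_fit()] object.
#' @return List of class `ddm_dic` with `dic`, `p_d`, `d_bar` and the count
#'   of non-finite deviance draws excluded (with a warning if any).
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "ddm_hfit"))
  draws <- as.matrix(fit)
  ll <- draws[, "log_lik"]
  ok <- is.finite(ll) & ll > -1e9 # guard the soft -Inf likelihood floor
  n_bad <- sum(!ok)
  if (n_bad > 0L)
    warning(n_bad, " draws with non-finite deviance excluded")
  d_bar <- mean(-2 * ll[ok])
  model <- fit$model
  th <- .subject_means(fit)
  d_hat <- -2 * hddm_loglik_cpp(th, model$sub_start, model$sub_end,
                                model$data$delta_m, model$data$delta_s,
                                model$data$rt_seconds, model$resp,
                                model$mcol, model$scol, model$zcol,
                                model$col_a, model$col_t0)
  p_d <- d_bar - d_hat
  structure(list(dic = d_bar + p_d, p_d = p_d, d_bar = d_bar,
                 n_excluded = n_bad), class = "ddm_dic")
}

#' @export
print.ddm_dic <- function(x, ...) {
  cat(sprintf("DIC = %.2f  (mean deviance %.2f, effective parameters %.2f)\n",
              x$dic, x$d_bar, x$p_d))
  invisible(x)
}

#' Posterior-predictive mean squared error of condition summaries
#'
#' For each simulation, one retained posterior draw is taken and the fitted
#' dataset's trials are re-simulated with those subject parameters; the
#' squared error between observed and simulated per-condition summaries (mean
#' proportion of harmful choices, and mean RT) is averaged across conditions
#' and simulations. Conditions are the source-by-destination cells present in
#' the data.
#'
#' @param fit a [ddm_fit()] object.
#' @param n_sims number of posterior-predictive simulations.
#' @param dt simulation step (s).
#' @param window response window (s).
#' @param seed optional seed.
#' @return Named vector `c(mse_choice, mse_rt)` (squared proportion units and
#'   squared seconds).
#' @export
posterior_predictive_mse <- function(fit, n_sims = 1000, dt = 0.002,
                                     window = 6, seed = NULL) {
  stopifnot(inherits(fit, "ddm_hfit"), n_sims >= 1)
  if (!is.null(seed)) set.seed(seed)
  data <- fit$model$data
  cond <- .condition_key(data)
  obs_choice <- tapply(data$response == "high", cond, mean)
  obs_rt <- tapply(data$rt_seconds, cond, mean)
  draws <- as.matrix(fit)
  se_choice <- se_rt <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    i <- sample.int(nrow(draws), 1L)
    sim <- .simulate_from_draw(fit, draws[i, ], dt, window)
    sim_choice <- tapply(sim$upper, cond, mean)
    sim_rt <- tapply(sim$rt, cond, mean)
    se_choice[s] <- mean((obs_choice - sim_choice)^2)
    se_rt[s] <- mean((obs_rt - sim_rt)^2)
  }
  c(mse_choice = mean(se_choice), mse_rt = mean(se_rt))
}

.condition_key <- function(data) {
  parts <- lapply(intersect(c("source", "destination"), names(data)),
                  function(f) data[[f]])
  if (length(parts) == 0L) rep("all", nrow(data)) else
    do.call(paste, c(parts, sep = "_"))
}

#' Posterior probability of exceeding a threshold
#'
#' Fraction of posterior samples strictly greater than `threshold`. When used
#' as a two-sided test report `min(p, 1 - p)`.
#'
#' @param samples draws of a scalar quantity.
#' @param threshold cutoff (default 0).
#' @param two_sided if `TRUE`, return `min(p, 1 - p)`.
#' @return Proportion in \[0, 1\].
#' @export
posterior_probability <- function(samples, threshold = 0, two_sided = FALSE) {
  if (length(samples) < 1L) stop("need at least one sample")
  p <- mean(samples > threshold)
  if (two_sided) min(p, 1 - p) else p
}

#' Draw-wise posterior of a parameter ratio
#'
#' Elementwise ratio of aligned posterior draws (same chain and iteration).
#' Ratios significantly different from 1 indicate condition effects on the
#' parameter. Warns when denominator draws cross zero, making the ratio
#' heavy-tailed.
#'
#' @param numerator,denominator aligned draw vectors.
#' @return Vector of ratio draws.
#' @export
ratio_posterior <- function(numerator, denominator) {
  if (length(numerator) != length(denominator))
    stop("draw vectors must be aligned (equal length)")
  s <- sign(denominator[which.max(abs(denominator))])
  n_cross <- sum(denominator * s <= 0)
  if (n_cross > 0L)
    warning(n_cross, " denominator draw(s) cross zero; ",
            "the ratio posterior is heavy-tailed")
  numerator / denominator
}

#' Highest-density interval of posterior samples
#'
#' The narrowest contiguous interval containing at least `mass` of the
#' samples (computed on the sorted draws, so its width never exceeds the
#' equal-tailed interval's).
#'
#' @param samples posterior draws.
#' @param mass probability mass (default 0.95).
#' @return `c(low, high)`.
#' @export
hdi <- function(samples, mass = 0.95) {
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)")
  x <- sort(samples)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1L], x[n]))
  starts <- seq_len(n - m + 1L)
  w <- x[starts + m - 1L] - x[starts]
  i <- which.min(w)
  c(x[i], x[i + m - 1L])
}

#' Rank fitted models by goodness of fit
#'
#' Orders fits of competing model specifications (on identical data) by DIC
#' and reports, when posterior-predictive MSEs are computed, whether the
#' choice-MSE and RT-MSE orderings disagree with the DIC ranking.
#'
#' @param fits named list of [ddm_fit()] objects on the same data.
#' @param n_sims posterior-predictive simulations per model (0 skips MSEs).
#' @param seed optional seed for the predictive simulations.
#' @param dt simulation step for predictive simulations (s).
#' @return Object of class `ddm_model_ranking`: a data frame sorted by DIC
#'   (best first) with a `disagreement` attribute.
#' @export
rank_models <- function(fits, n_sims = 0, seed = NULL, dt = 0.002) {
  if (length(fits) < 2L) stop("need at least two fitted models")
  if (is.null(names(fits)))
    names(fits) <- vapply(fits, function(f) f$spec$name, "")
  ids <- lapply(fits, function(f) f$model$data_id)
  if (!all(vapply(ids, identical, TRUE, y = ids[[1L]])))
    stop("models were fitted to different data")
  if (!is.null(seed)) set.seed(seed)
  dics <- lapply(fits, dic)
  tab <- data.frame(model = names(fits),
                    dic = vapply(dics, `[[`, 0, "dic"),
                    p_d = vapply(dics, `[[`, 0, "p_d"),
                    d_bar = vapply(dics, `[[`, 0, "d_bar"),
                    row.names = NULL)
  if (n_sims > 0L) {
    mse <- t(vapply(fits, posterior_predictive_mse, numeric(2L),
                    n_sims = n_sims, dt = dt))
    tab$mse_choice <- mse[, 1L]
    tab$mse_rt <- mse[, 2L]
  }
  tab <- tab[order(tab$dic), , drop = FALSE]
  rownames(tab) <- NULL
  disagreement <- character(0)
  if (n_sims > 0L) {
    if (is.unsorted(tab$mse_choice))
      disagreement <- c(disagreement, "mse_choice")
    if (is.unsorted(tab$mse_rt))
      disagreement <- c(disagreement, "mse_rt")
  }
  structure(tab, disagreement = disagreement,
            class = c("ddm_model_ranking", "data.frame"))
}

#' @export
print.ddm_model_ranking <- function(x, digits = 4, ...) {
  cat("Model ranking (lower DIC is better):\n")
  y <- as.data.frame(x)
  y[-1L] <- lapply(y[-1L], round, digits)
  print(y, row.names = FALSE)
  d <- attr(x, "disagreement")
  if (length(d) > 0L)
    cat("note: ordering by", paste(d, collapse = " and "),
        "disagrees with the DIC ranking\n")
  invisible(x)
}
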