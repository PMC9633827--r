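#' @export
print.ddm_hfit <- function(x, ...) {
  post <- x$posterior
  cat("Hierarchical multi-attribute DDM fit\n")
  cat("  spec:     ", x$spec$name, "\n")
  cat("  subjects: ", length(post$participants), "   records: ",
      nrow(x$model$data), "\n", sep = "")
  cat("  chains:   ", length(post$chains), " x ",
      post$n_iter - post$n_burn, " retained draws\n", sep = "")
  cat("  group-location posterior means:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.ddm_hfit <- function(object, type = c("group", "subject"), ...) {
  type <- match.arg(type)
  draws <- as.matrix(object)
  pt <- object$posterior$param_table
  if (type == "group") {
    out <- colMeans(draws[, paste0("mu_", pt$par), drop = FALSE])
    names(out) <- pt$par
  } else {
    cols <- as.vector(vapply(pt$par, function(p)
      paste0(p, "[", object$posterior$participants, "]"),
      character(length(object$posterior$participants))))
    out <- colMeans(draws[, cols, drop = FALSE])
  }
  out
}

#' Pool posterior draws across chains
#'
#' @param x a fitted `ddm_hfit` object.
#' @param ... unused.
#' @return Matrix of retained draws (all chains stacked), one column per
#'   parameter plus `log_lik`.
#' @export
as.matrix.ddm_hfit <- function(x, ...) {
  do.call(rbind, x$posterior$chains)
}

#' Summarise a hierarchical DDM fit
#'
#' Posterior mean, SD and 95% highest-density interval for every group-level
#' parameter, with the Gelman-Rubin statistic across chains.
#'
#' @param object a `ddm_hfit`.
#' @param prob mass of the highest-density interval.
#' @param ... unused.
#' @export
summary.ddm_hfit <- function(object, prob = 0.95, ...) {
  post <- object$posterior
  pt <- post$param_table
  cols <- c(paste0("mu_", pt$par), paste0("sigma_", pt$par))
  draws <- as.matrix(object)[, cols, drop = FALSE]
  his <- apply(draws, 2L, hdi, mass = prob)
  tab <- data.frame(parameter = cols, mean = colMeans(draws),
                    sd = apply(draws, 2L, sd),
                    hdi_low = his[1L, ], hdi_high = his[2L, ],
                    row.names = NULL)
  tab$rhat <- if (length(post$chains) >= 2L)
    unname(gelman_rubin(post$chains)[cols]) else NA_real_
  structure(list(table = tab, spec = object$spec$name,
                 n_subjects = length(post$participants),
                 n_records = nrow(object$model$data),
                 n_chains = length(post$chains), prob = prob),
            class = "summary.ddm_hfit")
}

#' @export
print.summary.ddm_hfit <- function(x, digits = 4, ...) {
  cat("Hierarchical DDM fit (", x$spec, "): ", x$n_subjects, " subjects, ",
      x$n_records, " records, ", x$n_chains, " chains\n", sep = "")
  tab <- x$table
  tab[-1L] <- lapply(tab[-1L], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predicted probability of the harmful choice per record
#'
#' Closed-form upper-boundary probability at the posterior mean of each
#' subject's parameters, one value per data record (or per `newdata` row if
#' supplied, matched by `participant_id` and condition labels).
#'
#' @param object a `ddm_hfit`.
#' @param newdata optional records with `participant_id`, `delta_m`,
#'   `delta_s` and condition columns.
#' @param ... unused.
#' @return Vector of probabilities of responding `"high"`.
#' @export
predict.ddm_hfit <- function(object, newdata = NULL, ...) {
  model <- object$model
  data <- if (is.null(newdata)) model$data else newdata
  pt <- model$param_table
  th <- .subject_means(object)
  sub <- match(data$participant_id, object$posterior$participants)
  if (anyNA(sub)) stop("unknown participant_id in newdata")
  mcol <- .record_cols(pt, "bm", object$spec$beta_m_by, data) + 1L
  scol <- .record_cols(pt, "bs", object$spec$beta_s_by, data) + 1L
  zcol <- .record_cols(pt, "z", object$spec$z_by, data) + 1L
  idx <- cbind(sub, mcol)
  v <- th[idx] * data$delta_m + th[cbind(sub, scol)] * data$delta_s
  a <- th[cbind(sub, model$col_a + 1L)]
  w <- ifelse(zcol == 0L, 0.5, th[cbind(sub, pmax(zcol, 1L))])
  x <- 2 * v * a
  ifelse(abs(x) < 1e-12, w, expm1(-x * w) / expm1(-x))
}

# posterior-mean subject parameter matrix (subjects x parameter labels)
.subject_means <- function(object) {
  post <- .post_of(object)
  pt <- post$param_table
  draws <- if (inherits(object, "ddm_hfit")) as.matrix(object) else
    do.call(rbind, post$chains)
  nsub <- length(post$participants)
  th <- matrix(0, nsub, nrow(pt))
  for (k in seq_len(nrow(pt))) {
    cols <- paste0(pt$par[k], "[", post$participants, "]")
    th[, k] <- colMeans(draws[, cols, drop = FALSE])
  }
  th
}

#' Posterior-predictive datasets from a fitted DDM
#'
#' For each simulation, draws one retained posterior sample and simulates a
#' full replicate of the fitted dataset's trials with those subject-level
#' parameters.
#'
#' @param object a `ddm_hfit`.
#' @param nsim number of replicate datasets.
#' @param seed optional seed.
#' @param dt simulation step (s).
#' @param window response window (s).
#' @param ... unused.
#' @return List of data frames, each the fitted records with simulated
#'   `response` and `rt_seconds`.
#' @export
simulate.ddm_hfit <- function(object, nsim = 1, seed = NULL, dt = 0.002,
                              window = 6, ...) {
  if (!is.null(seed)) set.seed(seed)
  draws <- as.matrix(object)
  out <- vector("list", nsim)
  for (s in seq_len(nsim)) {
    i <- sample.int(nrow(draws), 1L)
    sim <- .simulate_from_draw(object, draws[i, ], dt, window)
    rec <- object$model$data
    rec$response <- ifelse(sim$upper == 1, "high", "low")
    rec$rt_seconds <- sim$rt
    out[[s]] <- rec
  }
  out
}

# simulate the whole dataset once from a named draw vector
.simulate_from_draw <- function(object, draw, dt, window) {
  model <- object$model
  pt <- model$param_table
  post <- object$posterior
  data <- model$data
  sub <- match(data$participant_id, post$participants)
  th <- matrix(0, length(post$participants), nrow(pt))
  for (k in seq_len(nrow(pt)))
    th[, k] <- draw[paste0(pt$par[k], "[", post$participants, "]")]
  v <- th[cbind(sub, model$mcol + 1L)] * data$delta_m +
       th[cbind(sub, model$scol + 1L)] * data$delta_s
  a <- th[cbind(sub, model$col_a + 1L)]
  t0 <- th[cbind(sub, model$col_t0 + 1L)]
  w <- ifelse(model$zcol < 0L, 0.5, th[cbind(sub, pmax(model$zcol + 1L, 1L))])
  sim_dataset_cpp(v, a, w, t0, dt, window)
}

#' Diagnostic plots for a hierarchical DDM fit
#'
#' Trace plots (one line per chain) or posterior densities of the group
#' location parameters.
#'
#' @param x a `ddm_hfit`.
#' @param which `"trace"` or `"density"`.
#' @param ... passed to the underlying plotting functions.
#' @export
plot.ddm_hfit <- function(x, which = c("trace", "density"), ...) {
  which <- match.arg(which)
  post <- x$posterior
  pars <- paste0("mu_", post$param_table$par)
  op <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)),
                      mar = c(3, 3, 2, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    if (which == "trace") {
      m <- vapply(post$chains, function(ch) ch[, p],
                  numeric(nrow(post$chains[[1L]])))
      graphics::matplot(m, type = "l", lty = 1, main = p, xlab = "",
                        ylab = "", ...)
    } else {
      d <- stats::density(do.call(rbind, post$chains)[, p])
      plot(d, main = p, xlab = "", ylab = "", ...)
    }
  }
  invisible(x)
}
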