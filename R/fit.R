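#' Remove anticipatory responses before model fitting
#'
#' Drops all records with RT faster than 200 ms (outlier RTs this fast are
#' incompatible with the decision process plus non-decision time and distort
#' DDM estimation). The operation is idempotent and makes no other change.
#'
#' @param records choice records with `participant_id` and `rt_seconds`.
#' @param min_rt exclusion threshold in seconds (default 0.2).
#' @return The retained records, with an `"exclusions"` attribute: a data
#'   frame of per-participant excluded counts. Warns if any participant loses
#'   all their trials.
#' @export
preprocess_choices <- function(records, min_rt = 0.2) {
  if (any(records$rt_seconds <= 0)) stop("all RTs must be positive")
  fast <- records$rt_seconds < min_rt
  pid <- unique(records$participant_id)
  report <- data.frame(
    participant_id = pid,
    n_excluded = vapply(pid, function(p)
      sum(fast[records$participant_id == p]), 0L),
    n_retained = vapply(pid, function(p)
      sum(!fast[records$participant_id == p]), 0L))
  if (any(report$n_retained == 0L))
    warning("participant(s) with no retained trials: ",
            paste(report$participant_id[report$n_retained == 0L],
                  collapse = ", "))
  out <- records[!fast, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- report
  out
}

#' Assemble a hierarchical DDM model from a specification and data
#'
#' Builds the joint posterior definition: for every parameter label (boundary
#' separation, non-decision time, and each condition cell of the starting
#' point and drift weights the spec splits), a group location with a uniform
#' prior over the parameter's support and a group scale with a uniform prior,
#' with subject-level values drawn from the truncated-normal group
#' distribution and the Wiener first-passage likelihood at the bottom.
#'
#' @param spec a [ddm_model_spec()].
#' @param data cleaned choice records (see [preprocess_choices()]) with
#'   columns `participant_id`, `response`, `rt_seconds`, `delta_m`,
#'   `delta_s`, plus `source`/`destination` as required by the spec.
#' @param priors a [ddm_priors()].
#' @return Object of class `hddm_model`.
#' @export
build_hddm <- function(spec, data, priors = ddm_priors()) {
  stopifnot(inherits(spec, "ddm_model_spec"))
  need <- c("participant_id", "response", "rt_seconds", "delta_m", "delta_s")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0L)
    stop("data lacks required column(s): ", paste(miss, collapse = ", "))
  if (nrow(data) == 0L) stop("data is empty")
  if (!all(data$response %in% c("high", "low")))
    stop("response must be 'high' or 'low'")
  for (f in spec$factors_used) {
    if (!f %in% names(data) || length(unique(data[[f]])) < 2L)
      stop("configuration error: spec splits by '", f,
           "' but the data has no such 2-level factor")
    if (!all(data[[f]] %in% .factor_levels[[f]]))
      stop("'", f, "' labels must be in {",
           paste(.factor_levels[[f]], collapse = ", "), "}")
  }

  data <- data[order(match(data$participant_id,
                           unique(data$participant_id))), , drop = FALSE]
  pid <- unique(data$participant_id)
  sub <- match(data$participant_id, pid)
  pt <- .param_table(spec, priors)

  model <- list(
    spec = spec, priors = priors, param_table = pt,
    participants = pid, data = data,
    sub_start = as.integer(vapply(seq_along(pid),
      function(i) min(which(sub == i)), 0L) - 1L),
    sub_end = as.integer(vapply(seq_along(pid),
      function(i) max(which(sub == i)), 0L) - 1L),
    mcol = .record_cols(pt, "bm", spec$beta_m_by, data),
    scol = .record_cols(pt, "bs", spec$beta_s_by, data),
    zcol = .record_cols(pt, "z", spec$z_by, data),
    col_a = which(pt$base == "a") - 1L,
    col_t0 = which(pt$base == "t0") - 1L,
    resp = as.integer(data$response == "high"),
    data_id = c(n = nrow(data), rt_sum = round(sum(data$rt_seconds), 6),
                n_high = sum(data$response == "high")))
  class(model) <- "hddm_model"
  model
}

#' @export
print.hddm_model <- function(x, ...) {
  cat("Hierarchical DDM model (", x$spec$name, "): ",
      length(x$participants), " subjects, ", nrow(x$data), " records, ",
      nrow(x$param_table), " parameter labels\n", sep = "")
  invisible(x)
}

# initial values: neutral group locations, subject values jittered inside the
# support; t0 must start below each subject's fastest RT
.hddm_init <- function(model, jitter = 0) {
  pt <- model$param_table
  K <- nrow(pt)
  nsub <- length(model$participants)
  mu0 <- ifelse(pt$base == "a", 1.5,
         ifelse(pt$base == "t0", 0.3,
         ifelse(pt$base == "z", 0.5, 0)))
  if (jitter > 0)
    mu0 <- pmin(pmax(mu0 + rnorm(K, 0, jitter * (pt$hi - pt$lo)), pt$lo + 1e-3),
                pt$hi - 1e-3)
  sg0 <- rep(0.2, K)
  th0 <- matrix(rep(mu0, each = nsub), nsub, K)
  rtmin <- vapply(seq_len(nsub), function(i)
    min(model$data$rt_seconds[(model$sub_start[i] + 1):(model$sub_end[i] + 1)]),
    0)
  k_t0 <- model$col_t0 + 1L
  th0[, k_t0] <- pmax(pmin(th0[, k_t0], 0.8 * rtmin), pt$lo[k_t0])
  list(mu = mu0, sg = sg0, theta = th0)
}

#' Draw from the joint posterior of a hierarchical DDM
#'
#' Metropolis-within-Gibbs sampler with random-walk proposals, batch-adapted
#' during burn-in only (the transition kernel is fixed for the retained
#' draws). Any number of independent chains are run sequentially from
#' jittered starting points; results are deterministic given `seed`.
#'
#' @param model a [build_hddm()] object.
#' @param n_iter iterations per chain (including burn-in).
#' @param n_burn burn-in iterations discarded per chain.
#' @param n_chains number of chains (>= 2 recommended for diagnostics).
#' @param seed integer seed.
#' @param use_likelihood internal: `FALSE` samples the hierarchical prior
#'   (constant likelihood), for prior-recovery checks.
#' @return Object of class `hddm_post`: a list of per-chain draw matrices
#'   (columns: `mu_*` group locations, `sigma_*` group scales, subject values
#'   `par[id]`, and `log_lik`), plus acceptance rates.
#' @export
sample_hddm <- function(model, n_iter = 3000, n_burn = 1000, n_chains = 2,
                        seed = NULL, use_likelihood = TRUE) {
  stopifnot(inherits(model, "hddm_model"), n_iter > n_burn)
  if (!is.null(seed)) set.seed(seed)
  pt <- model$param_table
  nsub <- length(model$participants)
  labels <- c(paste0("mu_", pt$par), paste0("sigma_", pt$par),
              as.vector(vapply(pt$par, function(p)
                paste0(p, "[", model$participants, "]"),
                character(nsub))),
              "log_lik")
  chains <- vector("list", n_chains)
  accept <- vector("list", n_chains)
  for (ch in seq_len(n_chains)) {
    init <- .hddm_init(model, jitter = if (ch == 1L) 0 else 0.03)
    res <- hddm_mcmc_cpp(model$sub_start, model$sub_end,
                         model$data$delta_m, model$data$delta_s,
                         model$data$rt_seconds, model$resp,
                         model$mcol, model$scol, model$zcol,
                         model$col_a, model$col_t0,
                         as.matrix(model$param_table[, c("lo", "hi")]),
                         init$mu, init$sg, init$theta,
                         as.integer(n_iter), as.integer(n_burn),
                         model$priors$scale[1], model$priors$scale[2],
                         use_likelihood)
    colnames(res$draws) <- labels
    chains[[ch]] <- res$draws
    accept[[ch]] <- res$accept
  }
  structure(list(chains = chains, accept = accept, n_iter = n_iter,
                 n_burn = n_burn, param_table = pt,
                 participants = model$participants),
            class = "hddm_post")
}

#' Fit a hierarchical multi-attribute DDM
#'
#' The package's central model-fitting function: cleans the data (RT < 200 ms
#' exclusion), assembles the hierarchical model for the requested
#' specification, and samples its joint posterior by MCMC.
#'
#' @inheritParams sample_hddm
#' @param data choice records: `participant_id`, `response`
#'   (`"high"`/`"low"`), `rt_seconds`, `delta_m`, `delta_s`, plus
#'   `source`/`destination` columns for condition-split specs.
#' @param spec a [ddm_model_spec()]; defaults to the valuation-conflict model
#'   with source-specific drift weights.
#' @param priors a [ddm_priors()].
#' @param min_rt anticipatory-RT exclusion threshold, seconds.
#' @return Object of class `ddm_hfit`, with `print`, `summary`, `coef`,
#'   `predict`, `simulate` and `plot` methods.
#' @examples
#' \donttest{
#' study <- generate_choice_study(population_config("study1", n_subjects = 6,
#'                                                  n_trials = 40), seed = 1)
#' fit <- ddm_fit(study$records, ddm_model_spec("valuation_conflict"),
#'                n_iter = 600, n_burn = 200, n_chains = 2, seed = 1)
#' coef(fit)
#' }
#' @export
ddm_fit <- function(data, spec = ddm_model_spec("valuation_conflict"),
                    priors = ddm_priors(), n_iter = 3000, n_burn = 1000,
                    n_chains = 2, seed = NULL, min_rt = 0.2) {
  cleaned <- preprocess_choices(data, min_rt = min_rt)
  model <- build_hddm(spec, cleaned, priors)
  post <- sample_hddm(model, n_iter = n_iter, n_burn = n_burn,
                      n_chains = n_chains, seed = seed)
  structure(list(model = model, posterior = post,
                 exclusions = attr(cleaned, "exclusions"),
                 spec = spec, call = match.call()),
            class = "ddm_hfit")
}

#' Gelman-Rubin potential scale reduction across runs
#'
#' Classic split-free Gelman-Rubin statistic comparing within-run and
#' between-run variance of independent runs of the same model. Perfect
#' convergence gives values of 1; values above about 1.1 indicate
#' non-convergence.
#'
#' @param runs a list (length >= 2) of draw matrices with identical columns,
#'   or of [ddm_fit()] / [sample_hddm()] objects (chains are pooled per run;
#'   a single fitted object may also be supplied, in which case its chains
#'   are treated as the runs).
#' @return Named vector of R-hat values, one per parameter.
#' @export
gelman_rubin <- function(runs) {
  if (inherits(runs, "ddm_hfit") || inherits(runs, "hddm_post"))
    runs <- .post_of(runs)$chains
  mats <- lapply(runs, function(r) {
    if (inherits(r, "ddm_hfit") || inherits(r, "hddm_post"))
      as.matrix(do.call(rbind, .post_of(r)$chains))
    else as.matrix(r)
  })
  if (length(mats) < 2L)
    stop("need at least two runs to compute the Gelman-Rubin statistic")
  cols <- Reduce(intersect, lapply(mats, colnames))
  if (!is.null(cols)) {
    cols <- setdiff(cols, "log_lik")
    mats <- lapply(mats, function(m) m[, cols, drop = FALSE])
  }
  n <- min(vapply(mats, nrow, 0L))
  mats <- lapply(mats, function(m) m[seq_len(n), , drop = FALSE])
  m <- length(mats)
  means <- vapply(mats, colMeans, numeric(ncol(mats[[1L]])))
  vars <- vapply(mats, function(x) apply(x, 2L, var),
                 numeric(ncol(mats[[1L]])))
  if (is.null(dim(means))) { # single-parameter case
    means <- matrix(means, nrow = 1L)
    vars <- matrix(vars, nrow = 1L)
  }
  W <- rowMeans(vars)
  B <- n * apply(means, 1L, var)
  vhat <- (n - 1) / n * W + B / n
  rhat <- sqrt(vhat / W)
  names(rhat) <- colnames(mats[[1L]])
  rhat
}

# posterior accessor shared by methods
.post_of <- function(x) {
  if (inherits(x, "ddm_hfit")) x$posterior else x
}
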