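#' Population configuration for synthetic choice studies
#'
#' Describes the generating population of a synthetic study: the design
#' (which condition factors exist and how many trials each subject faces),
#' the generating model specification, and group-level means and standard
#' deviations for every DDM parameter (per condition cell where the spec
#' splits it). Subject parameters are drawn from normal distributions around
#' the group means, truncated to each parameter's support.
#'
#' The default group means are demonstration values chosen inside plausible
#' fitted ranges (e.g. a dirty/clean money-weight ratio around 0.85 in the
#' one-factor design, and source effects concentrated on the money weight for
#' profit but the shock weight for charity in the 2x2 design); they are not
#' estimates from any dataset.
#'
#' @param design `"study1"` (source factor only, 102 base trials, so 204
#'   decisions per subject) or `"study3"` (source x destination, 44 base
#'   trials, 176 decisions).
#' @param n_subjects number of simulated deciders (default 28 for study1,
#'   61 for study3).
#' @param spec generating [ddm_model_spec()]; defaults to the
#'   valuation-conflict model with the design's factors.
#' @param group_mean named list overriding entries of `a`, `t0`, `z`, `bm`,
#'   `bs`; `z`/`bm`/`bs` may be named per condition cell.
#' @param group_sd named list of group standard deviations (same names).
#' @param n_trials number of base trials (reused across condition cells).
#' @param window response window in seconds.
#' @param dt simulation step in seconds.
#' @param priors [ddm_priors()] supplying parameter supports for truncation.
#' @return Object of class `population_config`.
#' @export
population_config <- function(design = c("study1", "study3"),
                              n_subjects = NULL, spec = NULL,
                              group_mean = list(), group_sd = list(),
                              n_trials = NULL, window = 6, dt = 0.001,
                              priors = ddm_priors()) {
  design <- match.arg(design)
  if (is.null(n_subjects)) n_subjects <- if (design == "study1") 28L else 61L
  if (is.null(n_trials)) n_trials <- if (design == "study1") 102L else 44L
  factors <- if (design == "study1") "source" else c("source", "destination")
  if (is.null(spec)) spec <- ddm_model_spec("valuation_conflict",
                                            factors = factors)
  mean_default <- if (design == "study1") {
    list(a = 1.8, t0 = 0.4, z = 0.5,
         bm = c(dirty = 0.30, clean = 0.35),
         bs = c(dirty = -0.128, clean = -0.12))
  } else {
    list(a = 1.8, t0 = 0.4, z = 0.5,
         bm = c(dirty_profit = 0.26, clean_profit = 0.35,
                dirty_charity = 0.30, clean_charity = 0.30),
         bs = c(dirty_profit = -0.127, clean_profit = -0.12,
                dirty_charity = -0.11, clean_charity = -0.12))
  }
  sd_default <- list(a = 0.25, t0 = 0.08, z = 0.04, bm = 0.06, bs = 0.03)
  gm <- utils::modifyList(mean_default, group_mean)
  gs <- utils::modifyList(sd_default, group_sd)
  cfg <- list(design = design, n_subjects = as.integer(n_subjects),
              spec = spec, group_mean = gm, group_sd = gs,
              n_trials = as.integer(n_trials), window = window, dt = dt,
              priors = priors,
              cells = if (design == "study1") {
                data.frame(source = c("dirty", "clean"),
                           destination = "profit")
              } else {
                expand.grid(source = c("dirty", "clean"),
                            destination = c("profit", "charity"),
                            stringsAsFactors = FALSE)
              })
  class(cfg) <- "population_config"
  cfg
}

# group mean/sd for one parameter-table row
.group_value <- function(values, base, cell) {
  v <- values[[base]]
  if (length(v) == 1L && is.null(names(v))) return(unname(v))
  if (!cell %in% names(v))
    stop("group value for '", base, "' lacks an entry for cell '", cell, "'")
  unname(v[cell])
}

#' Draw subject-level parameters from the population
#'
#' Truncated-normal draws (inverse-CDF method, deterministic per seed) of
#' each subject's parameters around the configured group means, respecting
#' each parameter's support.
#'
#' @param config a [population_config()].
#' @param seed integer seed.
#' @return List with `theta` (subjects x parameter-label matrix), the
#'   parameter table, and a ground-truth `manifest`.
#' @export
sample_population <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pt <- .param_table(config$spec, config$priors)
  base_map <- c(a = "a", t0 = "t0", z = "z", bm = "bm", bs = "bs")
  theta <- matrix(NA_real_, config$n_subjects, nrow(pt),
                  dimnames = list(NULL, pt$par))
  for (k in seq_len(nrow(pt))) {
    m <- .group_value(config$group_mean, base_map[[pt$base[k]]], pt$cell[k])
    s <- .group_value(config$group_sd, base_map[[pt$base[k]]], pt$cell[k])
    if (s <= 0) {
      theta[, k] <- rep(m, config$n_subjects)
    } else {
      u <- runif(config$n_subjects, pnorm(pt$lo[k], m, s),
                 pnorm(pt$hi[k], m, s))
      theta[, k] <- qnorm(u, m, s)
    }
  }
  manifest <- list(design = config$design, seed = seed,
                   spec = config$spec$name,
                   group_mean = config$group_mean, group_sd = config$group_sd,
                   subjects = theta)
  list(theta = theta, param_table = pt, manifest = manifest)
}

# block structure: sections of 10 trials per condition, one section of each
# condition per block (presentation bookkeeping only; does not affect fits)
.presentation_order <- function(n_trials, n_cells) {
  per_block <- 10L
  n_sections <- ceiling(n_trials / per_block)
  ranks <- matrix(NA_integer_, n_trials, n_cells)
  pos <- 0L
  sections <- lapply(seq_len(n_cells), function(cc)
    split(sample.int(n_trials), ceiling(seq_len(n_trials) / per_block)))
  for (b in seq_len(n_sections)) {
    for (cc in sample.int(n_cells)) {
      idx <- sections[[cc]][[b]]
      ranks[idx, cc] <- pos + seq_along(idx)
      pos <- pos + length(idx)
    }
  }
  ranks
}

#' Generate a complete synthetic choice study
#'
#' Builds an indifference-point-matched trial set, draws a population of
#' subjects, and simulates every decision with the subject's
#' condition-appropriate parameters. The same base trial set is reused in
#' every condition cell (so condition effects are not confounded with the
#' trial set), and trials are arranged in blocks of 10 per condition. All
#' randomness flows from `seed` through named substreams, so the same
#' configuration and seed reproduce the dataset bit-identically.
#'
#' @param config a [population_config()].
#' @param seed integer seed.
#' @return List with `records` (choice records, one row per decision),
#'   `trials` (the base trial set), `subjects` (true subject parameters) and
#'   `manifest` (everything needed to re-simulate).
#' @examples
#' study <- generate_choice_study(population_config("study1",
#'   n_subjects = 4, n_trials = 20), seed = 1)
#' head(study$records)
#' @export
generate_choice_study <- function(config, seed = 1) {
  stopifnot(inherits(config, "population_config"))
  trials <- generate_trial_set(config$n_trials, variant = "study1",
                               seed = .substream_seed(seed, "trials"))
  pop <- sample_population(config, seed = .substream_seed(seed, "population"))
  set.seed(.substream_seed(seed, "choices"))
  pt <- pop$param_table
  mcol <- .record_cols(pt, "bm", config$spec$beta_m_by, config$cells) + 1L
  scol <- .record_cols(pt, "bs", config$spec$beta_s_by, config$cells) + 1L
  zcol <- .record_cols(pt, "z", config$spec$z_by, config$cells) + 1L
  k_a <- which(pt$base == "a")
  k_t0 <- which(pt$base == "t0")
  n_cells <- nrow(config$cells)
  nt <- config$n_trials
  recs <- vector("list", config$n_subjects)
  for (i in seq_len(config$n_subjects)) {
    th <- pop$theta[i, ]
    cell_recs <- vector("list", n_cells)
    for (cc in seq_len(n_cells)) {
      v <- th[mcol[cc]] * trials$delta_m + th[scol[cc]] * trials$delta_s
      w <- if (zcol[cc] == 0L) 0.5 else th[zcol[cc]]
      sim <- sim_dataset_cpp(v, rep(th[k_a], nt), rep(w, nt),
                             rep(th[k_t0], nt), config$dt, config$window)
      cell_recs[[cc]] <- data.frame(
        participant_id = paste0("s", i),
        trial_id = trials$trial_id,
        source = config$cells$source[cc],
        destination = config$cells$destination[cc],
        delta_m = trials$delta_m, delta_s = trials$delta_s,
        response = ifelse(sim$upper == 1, "high", "low"),
        rt_seconds = sim$rt,
        high_on_left = rep_len(c(TRUE, FALSE), nt))
    }
    ranks <- .presentation_order(nt, n_cells)
    for (cc in seq_len(n_cells))
      cell_recs[[cc]]$presentation <- ranks[, cc]
    ri <- do.call(rbind, cell_recs)
    recs[[i]] <- ri[order(ri$presentation), , drop = FALSE]
  }
  records <- do.call(rbind, recs)
  rownames(records) <- NULL
  manifest <- pop$manifest
  manifest$top_seed <- seed
  manifest$n_trials <- config$n_trials
  manifest$window <- config$window
  manifest$dt <- config$dt
  list(records = records, trials = trials, subjects = pop$theta,
       manifest = manifest)
}

#' Ground-truth fixed and random effects for synthetic blame studies
#'
#' Demonstration defaults: money decreases blame and shocks increase it (as
#' in third-party judgments of harm-for-money trade-offs), the profit
#' destination attracts more blame overall, and the destination modulates
#' both slopes so that the blame gap is coupled to destination effects on
#' valuation.
#'
#' @param beta0 intercept (rating units, charity condition).
#' @param beta1,beta2 slopes on `delta_m` (GBP) and `delta_s` (shocks).
#' @param beta3 condition effect (profit = 1).
#' @param beta4,beta5 condition interactions with `delta_m`, `delta_s`.
#' @param sd_u0 SD of rater random intercepts (rating units).
#' @param sd_e residual SD (rating units).
#' @return Named list of generating values.
#' @export
blame_truth <- function(beta0 = 45, beta1 = -1.9, beta2 = 1.7, beta3 = 10,
                        beta4 = 0.6, beta5 = 0.3, sd_u0 = 5, sd_e = 10) {
  list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
       beta4 = beta4, beta5 = beta5, sd_u0 = sd_u0, sd_e = sd_e)
}

#' Generate a synthetic between-rater blame study
#'
#' A 42-trial judged decision set (study2 option bounds) rated by independent
#' raters assigned to the profit or charity condition. Each rating is the
#' linear predictor plus a rater intercept and Gaussian residual, clipped to
#' the 0-100 scale; two attention-check rows are appended per rater
#' (configurably failed).
#'
#' @param n_profit,n_charity raters per condition.
#' @param truth generating values, see [blame_truth()].
#' @param seed integer seed.
#' @param fail_raters character vector of rater ids that fail the attention
#'   checks (respond 50 instead of the scale maximum).
#' @return List with `records` (including check rows), `trials` and
#'   `manifest`.
#' @export
generate_blame_study <- function(n_profit = 64, n_charity = 66,
                                 truth = blame_truth(), seed = 1,
                                 fail_raters = character(0)) {
  trials <- generate_trial_set(42, variant = "study2",
                               seed = .substream_seed(seed, "trials"))
  set.seed(.substream_seed(seed, "ratings"))
  raters <- data.frame(
    rater_id = c(paste0("p", seq_len(n_profit)),
                 paste0("c", seq_len(n_charity))),
    condition = rep(c("profit", "charity"), c(n_profit, n_charity)))
  raters$u0 <- rnorm(nrow(raters), 0, truth$sd_u0)
  out <- vector("list", nrow(raters))
  for (i in seq_len(nrow(raters))) {
    cond <- as.numeric(raters$condition[i] == "profit")
    mu <- truth$beta0 + raters$u0[i] +
      (truth$beta1 + cond * truth$beta4) * trials$delta_m +
      (truth$beta2 + cond * truth$beta5) * trials$delta_s +
      cond * truth$beta3
    rating <- pmin(pmax(mu + rnorm(42, 0, truth$sd_e), 0), 100)
    fails <- raters$rater_id[i] %in% fail_raters
    out[[i]] <- data.frame(
      rater_id = raters$rater_id[i], condition = raters$condition[i],
      delta_m = c(trials$delta_m, 10, 5),
      delta_s = c(trials$delta_s, 10, 5),
      rating = c(rating, if (fails) c(50, 50) else c(100, 100)),
      is_check = c(rep(FALSE, 42), TRUE, TRUE))
  }
  records <- do.call(rbind, out)
  rownames(records) <- NULL
  list(records = records, trials = trials,
       manifest = list(seed = seed, truth = truth,
                       n_profit = n_profit, n_charity = n_charity,
                       fail_raters = fail_raters))
}
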