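#' Read and write choice-record tables
#'
#' Tidy long-format CSV with one row per decision. Required columns:
#' `participant_id`, `trial_id`, `source`, `destination`, `response`
#' (`high`/`low`), `rt_seconds`; `delta_m`, `delta_s` and any extra columns
#' pass through. Condition labels are normalised to lower case. RTs are
#' validated as seconds: values that look like milliseconds are rejected
#' unless `rt_unit = "ms"` is given explicitly (no silent unit guessing).
#'
#' @param path CSV file path.
#' @param rt_unit `"s"` (default) or `"ms"`; `"ms"` divides RTs by 1000.
#' @return `read_choice_table`: validated records data frame.
#' @export
read_choice_table <- function(path, rt_unit = c("s", "ms")) {
  rt_unit <- match.arg(rt_unit)
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "trial_id", "source", "destination",
            "response", "rt_seconds")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  d$source <- tolower(d$source)
  d$destination <- tolower(d$destination)
  d$response <- tolower(d$response)
  bad <- which(!d$response %in% c("high", "low"))
  if (length(bad) > 0L)
    stop("invalid response at row ", bad[1L],
         " (must be 'high' or 'low'): ", d$response[bad[1L]])
  if (rt_unit == "ms") d$rt_seconds <- d$rt_seconds / 1000
  bad <- which(!is.finite(d$rt_seconds) | d$rt_seconds <= 0)
  if (length(bad) > 0L)
    stop("non-positive RT at row ", bad[1L], ": ", d$rt_seconds[bad[1L]])
  bad <- which(d$rt_seconds > 10)
  if (length(bad) > 0L)
    stop("RT at row ", bad[1L], " is ", d$rt_seconds[bad[1L]],
         " s; if the file is in milliseconds pass rt_unit = 'ms'")
  d
}

#' @rdname read_choice_table
#' @param records choice records to write.
#' @export
write_choice_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and write trial tables
#'
#' @param path CSV file path.
#' @param trials trial set from [generate_trial_set()].
#' @export
write_trial_table <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "s_low", "m_low", "s_high", "m_high",
            "delta_s", "delta_m")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  class(d) <- c("moral_trials", "data.frame")
  d
}

#' Read and write blame-rating tables
#'
#' Columns: `rater_id`, `condition` (`profit`/`charity`), `delta_m`,
#' `delta_s`, `rating` (0-100), optional logical `is_check`.
#'
#' @param path CSV file path.
#' @export
read_blame_table <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("rater_id", "condition", "delta_m", "delta_s", "rating")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0L)
    stop("missing column(s): ", paste(miss, collapse = ", "))
  d$condition <- tolower(d$condition)
  if (!all(d$condition %in% c("profit", "charity")))
    stop("condition must be 'profit' or 'charity'")
  bad <- which(d$rating < 0 | d$rating > 100)
  if (length(bad) > 0L)
    stop("rating outside 0-100 at row ", bad[1L])
  if (!"is_check" %in% names(d)) d$is_check <- FALSE
  d
}

#' @rdname read_blame_table
#' @param records blame records to write.
#' @export
write_blame_table <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}

# long-format posterior table (chain, iter, parameter, value)
.tidy_posterior <- function(fit) {
  post <- .post_of(fit)
  do.call(rbind, lapply(seq_along(post$chains), function(ch) {
    m <- post$chains[[ch]]
    data.frame(chain = ch, iter = rep(seq_len(nrow(m)), ncol(m)),
               parameter = rep(colnames(m), each = nrow(m)),
               value = as.vector(m))
  }))
}

#' Run the full analysis pipeline on a choice dataset
#'
#' Sequences the package's stages: anticipatory-RT exclusion, hierarchical
#' fits of a set of competing model specifications, DIC /
#' posterior-predictive model comparison, model-free behavioural summaries
#' and tests, and (when blame ratings are supplied and the design has a
#' destination factor) the blame mixed-effects model and the
#' blame-gap/temptation linkage. All outputs are written to `out_dir` as CSV
#' and JSON together with a run log recording the seed and package version;
#' a rerun with the same inputs and seed reproduces every output.
#'
#' @param choices choice records (see [read_choice_table()]).
#' @param blame optional blame records (see [read_blame_table()]).
#' @param out_dir output directory (created if absent).
#' @param specs character vector of model-spec names to fit and compare.
#' @param factors condition factors of the design, passed to the
#'   valuation-conflict family specs.
#' @param n_iter,n_burn,n_chains MCMC settings per model.
#' @param n_sims posterior-predictive simulations per model.
#' @param seed top-level seed (substreams are derived per stage).
#' @param min_rt anticipatory-RT threshold (s).
#' @return Invisibly, a list with the fits, ranking, behavioural stats and
#'   (if computed) blame/linkage results.
#' @export
run_pipeline <- function(choices, blame = NULL, out_dir,
                         specs = c("naive", "prosocial_default",
                                   "valuation_conflict", "hybrid"),
                         factors = "source", n_iter = 2000, n_burn = 600,
                         n_chains = 2, n_sims = 200, seed = 1,
                         min_rt = 0.2) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("moralddm version:",
                       as.character(utils::packageVersion("moralddm"))),
                 paste("seed:", seed), paste("date:", format(Sys.time())))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  cleaned <- stage("preprocess", preprocess_choices(choices, min_rt = min_rt))
  log_lines <- c(log_lines, paste("records retained:", nrow(cleaned), "of",
                                  nrow(choices)))

  fits <- list()
  for (sname in specs) {
    fits[[sname]] <- stage(paste0("fit:", sname), {
      sp <- ddm_model_spec(sname, factors = factors)
      ddm_fit(cleaned, sp, n_iter = n_iter, n_burn = n_burn,
              n_chains = n_chains,
              seed = .substream_seed(seed, paste0("fit_", sname)))
    })
    write.csv(.tidy_posterior(fits[[sname]]),
              file.path(out_dir, paste0("posterior_", sname, ".csv")),
              row.names = FALSE)
  }

  if (length(fits) >= 2L) {
    ranking <- stage("compare", rank_models(fits, n_sims = n_sims,
                       seed = .substream_seed(seed, "compare")))
  } else {
    ranking <- NULL
    log_lines <- c(log_lines, "compare stage skipped: single model fitted")
  }
  diag <- lapply(fits, function(f) {
    rh <- summary(f)$table$rhat
    list(rhat_max = if (all(is.na(rh))) NA else max(rh, na.rm = TRUE))
  })
  jsonlite::write_json(
    list(ranking = if (is.null(ranking)) list() else as.data.frame(ranking),
         disagreement = attr(ranking, "disagreement"),
         diagnostics = diag),
    file.path(out_dir, "ranking.json"), auto_unbox = TRUE, digits = NA)

  props <- stage("behavioral", harmful_choice_proportions(cleaned))
  write.csv(props, file.path(out_dir, "behavioral_summaries.csv"),
            row.names = FALSE)
  stats_report <- list()
  if (length(unique(cleaned$source)) == 2L) {
    wide <- tapply(props$prop_harmful,
                   list(props$participant_id, props$source), mean)
    stats_report$source_paired_t <-
      stage("behavioral", paired_t(wide[, "dirty"], wide[, "clean"]))
  }
  if (all(c("source", "destination") %in% names(cleaned)) &&
      length(unique(cleaned$destination)) == 2L) {
    stats_report$rm_anova <- stage("behavioral", rm_anova_2x2(props))
  }
  jsonlite::write_json(stats_report, file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA)

  blame_out <- NULL
  if (!is.null(blame)) {
    blame_out <- stage("blame", {
      kept <- filter_attention_checks(blame)
      full <- fit_blame_lmm(kept)
      per <- fit_blame_lmm(kept, per_condition = TRUE)
      list(full = full, per_condition = per,
           excluded = attr(kept, "excluded_raters"))
    })
    jsonlite::write_json(
      list(beta = as.list(blame_out$full$beta),
           var_u0 = blame_out$full$var_u0, var_e = blame_out$full$var_e,
           excluded_raters = blame_out$excluded),
      file.path(out_dir, "blame_lmm.json"), auto_unbox = TRUE, digits = NA)

    best <- if (is.null(ranking)) fits[[1L]] else fits[[ranking$model[1L]]]
    if ("destination" %in% best$spec$beta_m_by) {
      link <- stage("link", {
        w <- destination_weights(best)
        pts <- blame_gap_grid(blame_out$per_condition$profit,
                              blame_out$per_condition$charity)
        pts <- temptation_gap_grid(w$profit, w$charity, pts)
        pts
      })
      write.csv(link, file.path(out_dir, "link.csv"), row.names = FALSE)
      stats_report$link <- link_correlation(link)
      jsonlite::write_json(stats_report, file.path(out_dir, "stats.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      log_lines <- c(log_lines,
                     "link stage skipped: best model has no destination split")
    }
  } else {
    log_lines <- c(log_lines, "blame stages skipped: no rating data")
  }

  writeLines(log_lines, file.path(out_dir, "log.txt"))
  invisible(list(fits = fits, ranking = ranking, behavioral = stats_report,
                 blame = blame_out))
}

#' Destination-specific drift weights from a fitted model
#'
#' Posterior-mean drift weights for each destination, averaged across source
#' conditions when the fitted specification splits them (the inputs to the
#' temptation gap).
#'
#' @param fit a [ddm_fit()] whose spec splits drift weights by destination.
#' @return List with `profit` and `charity`, each `c(beta_m = , beta_s = )`.
#' @export
destination_weights <- function(fit) {
  co <- coef(fit)
  pt <- fit$posterior$param_table
  out <- list()
  for (dest in c("profit", "charity")) {
    pick <- function(base) {
      rows <- pt$base == base & grepl(dest, pt$cell, fixed = TRUE)
      if (!any(rows)) rows <- pt$base == base
      mean(co[pt$par[rows]])
    }
    out[[dest]] <- c(beta_m = pick("bm"), beta_s = pick("bs"))
  }
  out
}
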