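#' Apply the attention-check exclusion rule to blame ratings
#'
#' Raters were shown two attention-check items asking for a response at the
#' scale maximum (100). A rater who did not respond at the maximum on every
#' check is excluded entirely; check rows themselves are removed from the
#' analysis set.
#'
#' @param records blame records with `rater_id`, `rating` and logical
#'   `is_check`.
#' @return Non-check rows of passing raters, with attribute
#'   `"excluded_raters"`.
#' @export
filter_attention_checks <- function(records) {
  if (!"is_check" %in% names(records)) {
    attr(records, "excluded_raters") <- character(0)
    return(records)
  }
  chk <- records[records$is_check, , drop = FALSE]
  fail <- unique(chk$rater_id[chk$rating < 100])
  out <- records[!records$is_check &
                   !(records$rater_id %in% fail), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_raters") <- fail
  out
}

#' Fit the blame linear mixed-effects model
#'
#' Maximum-likelihood fit of the random-intercept regression of blame ratings
#' on the money difference, the shock difference, the destination condition
#' and its interactions:
#' \deqn{Blame = (\beta_0 + u_{0i}) + \beta_1 \Delta m + \beta_2 \Delta s +
#'   \beta_3 cond + \beta_4 (cond \times \Delta m) +
#'   \beta_5 (cond \times \Delta s)}
#' with condition dummy-coded profit = 1, charity = 0 (so \eqn{\beta_3 > 0}
#' means more blame for profit). With `per_condition = TRUE`, the
#' \eqn{\Delta m}/\eqn{\Delta s} model is fitted separately within each
#' condition (used for the blame-gap grid).
#'
#' @param records blame records with `rater_id`, `condition`
#'   (`"profit"`/`"charity"`), `delta_m`, `delta_s`, `rating`; any `is_check`
#'   rows are removed via [filter_attention_checks()] first.
#' @param per_condition fit separate per-condition models.
#' @return A `blame_lmm` object (fixed effects `beta`, variance components
#'   `var_u0`, `var_e`, and the underlying `lmerMod`), or a named list of two
#'   such objects when `per_condition = TRUE`.
#' @export
fit_blame_lmm <- function(records, per_condition = FALSE) {
  records <- filter_attention_checks(records)
  if (per_condition) {
    out <- lapply(c(profit = "profit", charity = "charity"), function(cc) {
      .fit_blame_one(records[records$condition == cc, , drop = FALSE],
                     condition = cc)
    })
    return(out)
  }
  for (cc in c("profit", "charity"))
    if (length(unique(records$rater_id[records$condition == cc])) < 2L)
      stop("need at least 2 raters per condition")
  records$cond <- as.numeric(records$condition == "profit")
  fit <- lme4::lmer(rating ~ delta_m + delta_s + cond + cond:delta_m +
                      cond:delta_s + (1 | rater_id),
                    data = records, REML = FALSE)
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  beta <- c(beta0 = unname(fe["(Intercept)"]),
            beta1 = unname(fe["delta_m"]), beta2 = unname(fe["delta_s"]),
            beta3 = unname(fe["cond"]), beta4 = unname(fe["delta_m:cond"]),
            beta5 = unname(fe["delta_s:cond"]))
  structure(list(beta = beta,
                 var_u0 = vc$vcov[vc$grp == "rater_id"],
                 var_e = vc$vcov[vc$grp == "Residual"],
                 se = .wald_se(fit),
                 n_raters = length(unique(records$rater_id)),
                 condition = NULL, model = fit),
            class = "blame_lmm")
}

.fit_blame_one <- function(records, condition) {
  if (length(unique(records$rater_id)) < 2L)
    stop("need at least 2 raters in the ", condition, " condition")
  fit <- lme4::lmer(rating ~ delta_m + delta_s + (1 | rater_id),
                    data = records, REML = FALSE)
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(beta = c(beta0 = unname(fe["(Intercept)"]),
                          delta_m = unname(fe["delta_m"]),
                          delta_s = unname(fe["delta_s"])),
                 var_u0 = vc$vcov[vc$grp == "rater_id"],
                 var_e = vc$vcov[vc$grp == "Residual"],
                 se = .wald_se(fit),
                 n_raters = length(unique(records$rater_id)),
                 condition = condition, model = fit),
            class = "blame_lmm")
}

.wald_se <- function(fit) {
  v <- as.matrix(stats::vcov(fit))
  setNames(sqrt(diag(v)), rownames(v))
}

#' @export
print.blame_lmm <- function(x, ...) {
  cat("Blame mixed-effects model (ML",
      if (!is.null(x$condition)) paste0(", ", x$condition, " condition"),
      "): ", x$n_raters, " raters\n", sep = "")
  print(round(x$beta, 4))
  cat(sprintf("random-intercept variance %.3f, residual variance %.3f\n",
              x$var_u0, x$var_e))
  invisible(x)
}

#' Predicted relative blame for an offer
#'
#' Slope-only prediction \eqn{\beta_1 \Delta m + \beta_2 \Delta s} from a
#' per-condition blame model (no intercept: the quantity feeding the blame
#' gap is relative across offers, not an absolute rating).
#'
#' @param fit a per-condition `blame_lmm` (from
#'   `fit_blame_lmm(..., per_condition = TRUE)`).
#' @param delta_m,delta_s offer differences; vectorised.
#' @return Predicted relative blame (rating units).
#' @export
predicted_blame <- function(fit, delta_m, delta_s) {
  if (is.null(fit$condition))
    stop("predicted_blame needs a per-condition blame model")
  fit$beta[["delta_m"]] * delta_m + fit$beta[["delta_s"]] * delta_s
}

#' Offer grid for the blame/temptation linkage
#'
#' Default grid of money and shock differences covering the task's offer
#' space.
#'
#' @param delta_s shock differences (default 1..20).
#' @param delta_m money differences (default 0.5, 1.0, ..., 19.5 GBP).
#' @return Data frame with all combinations.
#' @export
link_grid <- function(delta_s = 1:20, delta_m = seq(0.5, 19.5, by = 0.5)) {
  expand.grid(delta_m = delta_m, delta_s = delta_s)
}

#' Gap in predicted blame between profit and charity
#'
#' \eqn{Blame_{profit} - Blame_{charity}} at each grid point, from the two
#' per-condition blame models.
#'
#' @param fit_profit,fit_charity per-condition `blame_lmm` fits.
#' @param grid offer grid (see [link_grid()]).
#' @return The grid with a `blame_gap` column (rating units).
#' @export
blame_gap_grid <- function(fit_profit, fit_charity, grid = link_grid()) {
  grid$blame_gap <-
    predicted_blame(fit_profit, grid$delta_m, grid$delta_s) -
    predicted_blame(fit_charity, grid$delta_m, grid$delta_s)
  grid
}

#' Gap in "temptation" between profit and charity
#'
#' "Temptation" is the drift-weighted value of choosing the more harmful
#' option, \eqn{\beta_m \Delta m + \beta_s \Delta s}, computed from fitted
#' DDM drift weights; the gap contrasts the profit and charity destinations
#' at each grid point.
#'
#' @param weights_profit,weights_charity named vectors
#'   `c(beta_m = , beta_s = )` of destination-specific drift weights
#'   (averaged across source conditions when the fitted model splits them).
#' @param grid offer grid (see [link_grid()]).
#' @return The grid with a `temptation_gap` column (drift units).
#' @export
temptation_gap_grid <- function(weights_profit, weights_charity,
                                grid = link_grid()) {
  tp <- weights_profit[["beta_m"]] * grid$delta_m +
    weights_profit[["beta_s"]] * grid$delta_s
  tc <- weights_charity[["beta_m"]] * grid$delta_m +
    weights_charity[["beta_s"]] * grid$delta_s
  grid$temptation_gap <- tp - tc
  grid
}

#' Correlation between blame gap and temptation gap
#'
#' Pearson correlation, with two-sided p-value, between the profit-charity
#' blame gap and the profit-charity temptation gap over the offer grid: the
#' out-of-sample linkage between third-party judgments and the decision
#' model's valuation.
#'
#' @param points data frame with `blame_gap` and `temptation_gap` columns
#'   (combine [blame_gap_grid()] and [temptation_gap_grid()] on one grid).
#' @return List with `r` and `p_value`.
#' @export
link_correlation <- function(points) {
  if (nrow(points) < 3L) stop("need at least 3 grid points")
  if (var(points$blame_gap) == 0 || var(points$temptation_gap) == 0)
    stop("correlation undefined: a gap has zero variance")
  ct <- cor.test(points$blame_gap, points$temptation_gap)
  list(r = unname(ct$estimate), p_value = ct$p.value)
}
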