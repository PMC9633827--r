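#' Per-participant proportion of harmful choices by condition
#'
#' For each participant and condition cell, the proportion of trials on which
#' the high option (more money at the expense of more shocks) was chosen.
#'
#' @param records choice records with `participant_id`, `response` and
#'   whichever of `source`/`destination` are present.
#' @return Data frame with one row per participant x condition cell:
#'   `participant_id`, condition columns, `n_trials`, `prop_harmful`. Warns
#'   about empty cells (participants missing a condition).
#' @export
harmful_choice_proportions <- function(records) {
  facs <- intersect(c("source", "destination"), names(records))
  by <- c(list(participant_id = records$participant_id),
          setNames(lapply(facs, function(f) records[[f]]), facs))
  agg <- aggregate(records$response == "high", by = by,
                   FUN = function(x) c(n = length(x), p = mean(x)))
  out <- agg[names(by)]
  out$n_trials <- agg$x[, "n"]
  out$prop_harmful <- agg$x[, "p"]
  n_cells <- prod(vapply(facs, function(f) length(unique(records[[f]])), 0L))
  expected <- length(unique(records$participant_id)) * max(n_cells, 1L)
  if (nrow(out) < expected)
    warning("missing participant x condition cells: ",
            expected - nrow(out), " empty")
  out[do.call(order, out[names(by)]), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Paired t-test
#'
#' Classical two-sided paired t-test on matched per-subject values,
#' `df = n - 1`.
#'
#' @param x,y per-subject values of equal length (>= 2).
#' @return List with `t`, `df`, `p`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must be matched vectors of length >= 2")
  d <- x - y
  if (var(d) == 0)
    stop("zero variance of the paired differences: t is undefined")
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Two-by-two repeated-measures ANOVA on choice proportions
#'
#' Within-subject ANOVA of `prop_harmful` with source (dirty vs clean) and
#' destination (profit vs charity) as factors; each effect is tested against
#' its own subject-by-effect error stratum with `df = (1, n - 1)`.
#'
#' @param summaries output of [harmful_choice_proportions()] on a 2x2 design;
#'   every participant must have all four cells.
#' @return Data frame with rows `source`, `destination`, `source:destination`
#'   and columns `F`, `df1`, `df2`, `p`.
#' @export
rm_anova_2x2 <- function(summaries) {
  need <- c("participant_id", "source", "destination", "prop_harmful")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  tab <- table(summaries$participant_id)
  if (length(unique(summaries$source)) != 2L ||
      length(unique(summaries$destination)) != 2L ||
      any(tab != 4L))
    stop("each participant needs the complete 2x2 of condition cells")
  d <- data.frame(pid = factor(summaries$participant_id),
                  source = factor(summaries$source),
                  destination = factor(summaries$destination),
                  y = summaries$prop_harmful)
  fit <- aov(y ~ source * destination +
               Error(pid / (source * destination)), data = d)
  s <- summary(fit)
  eff <- c("source", "destination", "source:destination")
  out <- data.frame(effect = eff, F = NA_real_, df1 = NA_real_,
                    df2 = NA_real_, p = NA_real_)
  for (stratum in s) {
    st <- stratum[[1L]]
    rn <- trimws(rownames(st))
    for (e in intersect(eff, rn)) {
      i <- match(e, rn)
      j <- match(e, out$effect)
      out$F[j] <- st[i, "F value"]
      out$df1[j] <- st[i, "Df"]
      out$df2[j] <- st[rn == "Residuals", "Df"]
      out$p[j] <- st[i, "Pr(>F)"]
    }
  }
  out
}
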