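#' Model specification: which parameters vary by condition
#'
#' Defines the mapping from DDM parameters to condition factors, i.e. the
#' member of the model family being fitted:
#' \describe{
#'   \item{`naive`}{no parameter varies by condition (baseline; the starting
#'     point is fixed at the unbiased midpoint).}
#'   \item{`prosocial_default`}{separate starting points per money source
#'     (a pre-attribute response bias); drift weights pooled.}
#'   \item{`valuation_conflict`}{separate drift weights on money and shocks
#'     per condition cell (`factors`); starting point fixed at 0.5.}
#'   \item{`vc_money`, `vc_shock`}{valuation-conflict variants splitting only
#'     one attribute's weight.}
#'   \item{`hybrid`}{the valuation-conflict drift weights plus source-specific
#'     starting points.}
#'   \item{`custom`}{explicit `beta_m_by` / `beta_s_by` / `z_by` factor sets.}
#' }
#'
#' @param name model family member (see details).
#' @param factors condition factors the drift weights split by, a subset of
#'   `c("source", "destination")`; `"source"` for a Study-1-style design,
#'   `c("source", "destination")` for a 2x2 design.
#' @param beta_m_by,beta_s_by,z_by explicit factor sets (used by `custom`).
#' @return Object of class `ddm_model_spec`.
#' @examples
#' ddm_model_spec("valuation_conflict", factors = "source")
#' ddm_model_spec("prosocial_default")
#' @export
ddm_model_spec <- function(name = c("valuation_conflict", "naive",
                                    "prosocial_default", "vc_money",
                                    "vc_shock", "hybrid", "custom"),
                           factors = "source",
                           beta_m_by = character(), beta_s_by = character(),
                           z_by = character()) {
  name <- match.arg(name)
  ok <- c("source", "destination")
  for (f in list(factors, beta_m_by, beta_s_by, z_by))
    if (!all(f %in% ok))
      stop("condition factors must be a subset of {source, destination}")
  spec <- switch(name,
    naive = list(beta_m_by = character(), beta_s_by = character(),
                 z_by = character()),
    prosocial_default = list(beta_m_by = character(), beta_s_by = character(),
                             z_by = "source"),
    valuation_conflict = list(beta_m_by = factors, beta_s_by = factors,
                              z_by = character()),
    vc_money = list(beta_m_by = factors, beta_s_by = character(),
                    z_by = character()),
    vc_shock = list(beta_m_by = character(), beta_s_by = factors,
                    z_by = character()),
    hybrid = list(beta_m_by = factors, beta_s_by = factors, z_by = "source"),
    custom = list(beta_m_by = beta_m_by, beta_s_by = beta_s_by, z_by = z_by))
  spec$name <- name
  spec$factors_used <- unique(c(spec$beta_m_by, spec$beta_s_by, spec$z_by))
  class(spec) <- "ddm_model_spec"
  spec
}

#' @export
print.ddm_model_spec <- function(x, ...) {
  fmt <- function(f) if (length(f) == 0L) "(pooled)" else
    paste(f, collapse = " x ")
  cat("DDM model spec:", x$name, "\n")
  cat("  beta_m by:", fmt(x$beta_m_by), "\n")
  cat("  beta_s by:", fmt(x$beta_s_by), "\n")
  cat("  z      by:", if (length(x$z_by) == 0L) "(fixed at 0.5)" else
    fmt(x$z_by), "\n")
  invisible(x)
}

#' Prior intervals for the hierarchical fit
#'
#' All priors are uniform over generously wide intervals: group locations are
#' uniform over each parameter's support and group scales uniform over
#' `scale`. Subject-level parameters are normal around the group location,
#' truncated to the support.
#'
#' @param a,z,t0,beta_m,beta_s length-2 support intervals for boundary
#'   separation, relative starting point, non-decision time (s), and the two
#'   drift weights (per GBP / per shock, in diffusion-noise units).
#' @param scale interval for the group standard deviations.
#' @return Object of class `ddm_priors`.
#' @export
ddm_priors <- function(a = c(0.3, 6), z = c(0.05, 0.95), t0 = c(0.05, 1.5),
                       beta_m = c(-3, 3), beta_s = c(-3, 3),
                       scale = c(0.01, 3)) {
  pr <- list(a = a, z = z, t0 = t0, beta_m = beta_m, beta_s = beta_s,
             scale = scale)
  for (p in pr) {
    if (length(p) != 2L || !all(is.finite(p)) || p[1] >= p[2])
      stop("each prior interval must be a finite (lo, hi) pair")
  }
  class(pr) <- "ddm_priors"
  pr
}

# parameter bookkeeping: one row per sampled parameter column
.param_table <- function(spec, priors) {
  base <- c("a", "t0")
  cell <- c("", "")
  if (length(spec$z_by) > 0L) {
    zc <- .cells(spec$z_by)
    base <- c(base, rep("z", length(zc)))
    cell <- c(cell, zc)
  }
  mc <- .cells(spec$beta_m_by)
  sc <- .cells(spec$beta_s_by)
  base <- c(base, rep("bm", length(mc)), rep("bs", length(sc)))
  cell <- c(cell, mc, sc)
  supp <- list(a = priors$a, t0 = priors$t0, z = priors$z,
               bm = priors$beta_m, bs = priors$beta_s)
  lab <- ifelse(cell == "", base, paste(base, cell, sep = "_"))
  data.frame(par = lab, base = base, cell = cell,
             lo = vapply(base, function(b) supp[[b]][1], 0),
             hi = vapply(base, function(b) supp[[b]][2], 0),
             row.names = NULL)
}

# per-record column index (0-based) into the parameter table for one base
# parameter; -1 when the parameter is not sampled (fixed z)
.record_cols <- function(pt, base, by, records) {
  rows <- which(pt$base == base)
  if (length(rows) == 0L) return(rep(-1L, nrow(records)))
  if (length(by) == 0L) return(rep(rows[1L] - 1L, nrow(records)))
  by <- intersect(names(.factor_levels), by)
  key <- do.call(paste, c(lapply(by, function(f) records[[f]]), sep = "_"))
  idx <- match(key, pt$cell[rows])
  if (anyNA(idx)) stop("records contain condition labels outside the model ",
                       "specification for ", base)
  as.integer(rows[idx] - 1L)
}
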