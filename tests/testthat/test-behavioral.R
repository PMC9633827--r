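test_that("harmful-choice proportions count upper responses per cell", {
  rec <- data.frame(
    participant_id = rep("s1", 102 * 2),
    source = rep(c("dirty", "clean"), each = 102),
    destination = "profit",
    response = c(rep(c("high", "low"), c(51, 51)),
                 rep(c("high", "low"), c(30, 72))))
  out <- harmful_choice_proportions(rec)
  expect_equal(out$prop_harmful[out$source == "dirty"], 0.5)
  expect_equal(out$prop_harmful[out$source == "clean"], 30 / 102)
  # all-low responder
  rec$response <- "low"
  expect_true(all(harmful_choice_proportions(rec)$prop_harmful == 0))
})

test_that("proportions agree with a group-by counting oracle", {
  set.seed(14)
  rec <- data.frame(
    participant_id = sample(paste0("s", 1:5), 200, replace = TRUE),
    source = sample(c("dirty", "clean"), 200, replace = TRUE),
    destination = sample(c("profit", "charity"), 200, replace = TRUE),
    response = sample(c("high", "low"), 200, replace = TRUE))
  out <- harmful_choice_proportions(rec)
  for (i in seq_len(nrow(out))) {
    sel <- rec$participant_id == out$participant_id[i] &
      rec$source == out$source[i] & rec$destination == out$destination[i]
    expect_equal(out$prop_harmful[i], mean(rec$response[sel] == "high"))
    expect_equal(out$n_trials[i], sum(sel))
  }
})

test_that("paired t matches the direct formula and rejects degenerate input", {
  set.seed(3)
  x <- rnorm(10); y <- rnorm(10)
  got <- paired_t(x, y)
  expect_equal(got$t, ref_paired_t(x, y), tolerance = 1e-10)
  expect_equal(got$df, 9)
  same <- rnorm(5)
  expect_error(paired_t(same, same), "zero variance")
  expect_error(paired_t(1:4, (1:4) - 1), "zero variance") # diffs all 1
  shifted <- paired_t(c(1, 2, 3, 5), c(0, 1, 2, 3))
  expect_gt(shifted$t, 0)
})

test_that("x = y gives t = 0, p = 1 once noise breaks the tie variance", {
  x <- c(1, 2, 3, 4)
  y <- c(4, 3, 2, 1)
  both <- paired_t(c(x, y), c(y, x)) # antisymmetric: mean difference 0
  expect_equal(both$t, 0, tolerance = 1e-12)
  expect_equal(both$p, 1, tolerance = 1e-12)
})

test_that("repeated-measures ANOVA matches a hand sums-of-squares
           computation on a small fixture", {
  d <- expand.grid(participant_id = paste0("s", 1:4),
                   source = c("dirty", "clean"),
                   destination = c("profit", "charity"),
                   stringsAsFactors = FALSE)
  set.seed(9)
  d$prop_harmful <- round(runif(nrow(d)), 3)
  got <- rm_anova_2x2(d)

  # direct within-subject F for each effect from difference scores:
  # for a 2-level factor, F = t^2 on the per-subject marginal differences
  wide <- function(f) tapply(d$prop_harmful, list(d$participant_id, d[[f]]),
                             mean)
  for (eff in c("source", "destination")) {
    w <- wide(eff)
    tt <- ref_paired_t(w[, 1], w[, 2])
    expect_equal(got$F[got$effect == eff], tt^2, tolerance = 1e-8)
  }
  # interaction: difference of source differences across destinations
  dd <- tapply(d$prop_harmful, list(d$participant_id, d$source,
                                    d$destination), mean)
  inter <- (dd[, "dirty", "profit"] - dd[, "clean", "profit"]) -
    (dd[, "dirty", "charity"] - dd[, "clean", "charity"])
  t_int <- mean(inter) / (sd(inter) / sqrt(length(inter)))
  expect_equal(got$F[got$effect == "source:destination"], t_int^2,
               tolerance = 1e-8)
  expect_true(all(got$df1 == 1) && all(got$df2 == 3))
})

test_that("an additive destination shift leaves the interaction and source
           statistics unchanged", {
  d <- expand.grid(participant_id = paste0("s", 1:6),
                   source = c("dirty", "clean"),
                   destination = c("profit", "charity"),
                   stringsAsFactors = FALSE)
  set.seed(4)
  d$prop_harmful <- runif(nrow(d), 0.2, 0.8)
  base <- rm_anova_2x2(d)
  shifted <- d
  shifted$prop_harmful <- d$prop_harmful +
    0.15 * (d$destination == "profit")
  got <- rm_anova_2x2(shifted)
  # a pure destination shift cannot create source or interaction effects
  for (eff in c("source", "source:destination")) {
    expect_equal(got$F[got$effect == eff], base$F[base$effect == eff],
                 tolerance = 1e-8)
  }
  expect_false(isTRUE(all.equal(got$F[got$effect == "destination"],
                                base$F[base$effect == "destination"])))
  expect_error(rm_anova_2x2(d[-1, ]), "complete")
})

test_that("a crossover interaction is detected at realistic sample size", {
  hits <- 0
  for (seed in 1:3) {
    set.seed(seed)
    n <- 60
    d <- expand.grid(participant_id = sprintf("s%02d", 1:n),
                     source = c("dirty", "clean"),
                     destination = c("profit", "charity"),
                     stringsAsFactors = FALSE)
    mu <- 0.45 + 0.05 * (d$source == "clean") *
      ifelse(d$destination == "profit", 1, -1)
    d$prop_harmful <- pmin(pmax(mu + rnorm(nrow(d), 0, 0.12), 0), 1)
    got <- rm_anova_2x2(d)
    if (got$p[got$effect == "source:destination"] < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 2)
})
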