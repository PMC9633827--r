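test_that("attention-check filter removes exactly the flagged raters", {
  bs <- generate_blame_study(6, 6, seed = 2,
                             fail_raters = c("p2", "c5"))
  kept <- filter_attention_checks(bs$records)
  expect_setequal(attr(kept, "excluded_raters"), c("p2", "c5"))
  expect_false(any(kept$is_check))
  expect_setequal(unique(kept$rater_id),
                  setdiff(unique(bs$records$rater_id), c("p2", "c5")))
  expect_equal(nrow(kept), 10 * 42)
})

test_that("noise-free ratings are recovered exactly by the mixed model", {
  truth <- blame_truth(beta0 = 50, beta1 = -1.5, beta2 = 1.2, beta3 = 8,
                       beta4 = 0.4, beta5 = -0.3, sd_u0 = 0, sd_e = 0)
  bs <- generate_blame_study(5, 5, truth = truth, seed = 3)
  # keep ratings strictly inside the scale so clipping cannot bite
  expect_true(all(bs$records$rating[!bs$records$is_check] > 0 &
                    bs$records$rating[!bs$records$is_check] < 100))
  # a zero-residual design makes lme4's gradient checks complain; the
  # estimates themselves are exact
  fit <- suppressWarnings(suppressMessages(fit_blame_lmm(bs$records)))
  want <- unlist(truth[paste0("beta", 0:5)])
  expect_equal(unname(fit$beta), unname(want), tolerance = 1e-6)
})

test_that("condition dummy coding: swapping labels flips the condition
           effect's sign", {
  bs <- generate_blame_study(8, 8, seed = 5)
  rec <- bs$records
  fit <- fit_blame_lmm(rec)
  swapped <- rec
  swapped$condition <- ifelse(rec$condition == "profit", "charity", "profit")
  fit2 <- fit_blame_lmm(swapped)
  expect_equal(fit$beta[["beta3"]], -fit2$beta[["beta3"]], tolerance = 1e-6)
  expect_equal(fit$beta[["beta4"]], -fit2$beta[["beta4"]], tolerance = 1e-6)
})

test_that("fixed effects are recovered within their Wald intervals", {
  truth <- blame_truth(beta1 = -1.9, beta2 = 1.7, sd_u0 = 5, sd_e = 10)
  ok <- 0
  for (seed in 1:2) {
    bs <- generate_blame_study(30, 30, truth = truth, seed = seed)
    fit <- fit_blame_lmm(bs$records)
    want <- unlist(truth[paste0("beta", 0:5)])
    inside <- abs(fit$beta - want) <= 1.96 * fit$se
    if (all(inside)) ok <- ok + 1
  }
  expect_gte(ok, 1)
})

test_that("with vanishing random-intercept variance the fit matches OLS", {
  truth <- blame_truth(sd_u0 = 0, sd_e = 8)
  bs <- generate_blame_study(10, 10, truth = truth, seed = 7)
  rec <- filter_attention_checks(bs$records)
  rec$cond <- as.numeric(rec$condition == "profit")
  fit <- suppressWarnings(suppressMessages(fit_blame_lmm(bs$records)))
  ols <- lm(rating ~ delta_m + delta_s + cond + cond:delta_m + cond:delta_s,
            data = rec)
  expect_lt(max(abs(fit$beta - coef(ols))), 1e-4)
})

test_that("predicted blame and the gap grids are the stated linear forms", {
  fp <- structure(list(beta = c(beta0 = 1, delta_m = -1, delta_s = 2),
                       condition = "profit"), class = "blame_lmm")
  fc <- structure(list(beta = c(beta0 = 1, delta_m = -0.5, delta_s = 1.5),
                       condition = "charity"), class = "blame_lmm")
  expect_equal(predicted_blame(fp, 0, 0), 0)
  expect_equal(predicted_blame(fp, 3, 4), -1 * 3 + 2 * 4)
  # linearity over a grid
  g <- link_grid(delta_s = 1:3, delta_m = c(1, 2))
  expect_equal(predicted_blame(fp, 2 * g$delta_m, g$delta_s) -
                 predicted_blame(fp, g$delta_m, g$delta_s),
               -1 * g$delta_m)
  # gap grids: identical fits give zero, hand computation on 3 points
  gg0 <- blame_gap_grid(fp, fp, g)
  expect_true(all(gg0$blame_gap == 0))
  g3 <- data.frame(delta_m = c(1, 2, 3), delta_s = c(3, 2, 1))
  gg <- blame_gap_grid(fp, fc, g3)
  expect_equal(gg$blame_gap, (-1 + 0.5) * g3$delta_m + (2 - 1.5) * g3$delta_s)
  tg <- temptation_gap_grid(c(beta_m = 0.3, beta_s = -0.1),
                            c(beta_m = 0.3, beta_s = -0.1), g3)
  expect_true(all(tg$temptation_gap == 0))
  tg2 <- temptation_gap_grid(c(beta_m = 0.35, beta_s = -0.1),
                             c(beta_m = 0.3, beta_s = -0.1), g3)
  expect_equal(tg2$temptation_gap, 0.05 * g3$delta_m)
})

test_that("link correlation is Pearson's r on the gap pairs", {
  g <- link_grid(delta_s = 1:5, delta_m = c(1, 4))
  g$blame_gap <- g$delta_m - 0.2 * g$delta_s
  g$temptation_gap <- 2 * g$blame_gap
  expect_equal(link_correlation(g)$r, 1)
  set.seed(11)
  g$temptation_gap <- rnorm(nrow(g))
  expect_equal(link_correlation(g)$r,
               ref_pearson(g$blame_gap, g$temptation_gap),
               tolerance = 1e-12)
  g$temptation_gap <- 0
  expect_error(link_correlation(g), "zero variance")
})
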