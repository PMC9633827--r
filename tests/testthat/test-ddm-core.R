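p0 <- ddm_params(a = 1.5, t0 = 0.3, beta_m = 0.3, beta_s = -0.1, z = 0.4)

test_that("drift rate is the linear attribute combination", {
  expect_equal(drift_rate(p0, 2, 4), 0.3 * 2 - 0.1 * 4)
  expect_equal(drift_rate(p0, 0, 0), 0)
  # invariance to delta_s when its weight is zero
  pz <- ddm_params(a = 1, t0 = 0.2, beta_m = 0.5, beta_s = 0)
  grid <- expand.grid(dm = c(1, 5, 10), ds = c(1, 10, 20))
  expect_equal(drift_rate(pz, grid$dm, grid$ds), 0.5 * grid$dm)
  # additivity in delta_m
  expect_equal(drift_rate(p0, 3 + 4, 2),
               drift_rate(p0, 3, 2) + drift_rate(p0, 4, 0))
})

test_that("condition-named weights resolve by source/destination labels", {
  p <- ddm_params(a = 1.5, t0 = 0.3,
                  beta_m = c(dirty = 0.2, clean = 0.4), beta_s = -0.1)
  rec <- data.frame(source = c("dirty", "clean"))
  expect_equal(drift_rate(p, c(10, 10), c(0, 0), rec), c(2, 4))
  bad <- data.frame(source = c("dirty", "odd"))
  expect_error(drift_rate(p, c(1, 1), c(0, 0), bad), "cannot match")
})

test_that("choice probability has the closed form and its symmetries", {
  p <- ddm_params(a = 2, t0 = 0.3, beta_m = 0, beta_s = 0, z = 0.5)
  expect_equal(choice_probability(p, 0), 0.5)
  expect_equal(choice_probability(p, 1), (1 - exp(-2)) / (1 - exp(-4)))
  # continuity at v = 0
  expect_lt(abs(choice_probability(p, 1e-9) - choice_probability(p, 0)), 1e-6)
  # reflection symmetry: negate drift and mirror the start
  pa <- ddm_params(a = 1.7, t0 = 0.3, beta_m = 0, beta_s = 0, z = 0.35)
  pb <- ddm_params(a = 1.7, t0 = 0.3, beta_m = 0, beta_s = 0, z = 0.65)
  for (v in c(-1.2, -0.3, 0.4, 2)) {
    expect_equal(choice_probability(pa, v), 1 - choice_probability(pb, -v),
                 tolerance = 1e-12)
  }
})

test_that("choice probability equals the integrated upper-boundary density", {
  p <- ddm_params(a = 1.5, t0 = 0.3, beta_m = 0, beta_s = 0, z = 0.4)
  for (v in c(-0.8, 0, 0.9)) {
    iu <- integrate(function(t) ddm_fpt_density(t, "upper", p, v),
                    p$t0, Inf, rel.tol = 1e-9)$value
    expect_equal(iu, choice_probability(p, v), tolerance = 1e-6)
  }
})

test_that("first-passage densities vanish before t0 and normalise to one", {
  p <- ddm_params(a = 1.5, t0 = 0.3, beta_m = 0, beta_s = 0, z = 0.4)
  expect_equal(ddm_fpt_density(p$t0 - 0.05, "upper", p, 1), 0)
  expect_equal(ddm_fpt_density(p$t0, "lower", p, 1), 0)
  v <- 0.8
  iu <- integrate(function(t) ddm_fpt_density(t, "upper", p, v),
                  p$t0, Inf, rel.tol = 1e-9)$value
  il <- integrate(function(t) ddm_fpt_density(t, "lower", p, v),
                  p$t0, Inf, rel.tol = 1e-9)$value
  expect_equal(iu + il, 1, tolerance = 1e-4)
})

test_that("density matches an independent large-time series to 1e-8", {
  p <- ddm_params(a = 1.4, t0 = 0.25, beta_m = 0, beta_s = 0, z = 0.45)
  ts <- seq(0.45, 3.5, by = 0.25)
  for (v in c(-1, 0.3, 1.2)) {
    for (b in c("upper", "lower")) {
      got <- ddm_fpt_density(ts, b, p, v)
      want <- vapply(ts, ref_fpt, 0, upper = (b == "upper"), v = v,
                     a = p$a, w = p$z, t0 = p$t0)
      expect_lt(max(abs(got - want)), 1e-8)
    }
  }
})

test_that("log-likelihood composes per-record densities", {
  set.seed(7)
  trials <- data.frame(delta_m = runif(20, 0.5, 15),
                       delta_s = sample(1:20, 20, replace = TRUE))
  p <- ddm_params(a = 1.6, t0 = 0.3, beta_m = 0.25, beta_s = -0.1)
  rec <- simulate_ddm_trials(p, trials, seed = 1)
  rec <- cbind(trials, rec)
  # single record = log density
  one <- rec[3, , drop = FALSE]
  v1 <- drift_rate(p, one$delta_m, one$delta_s)
  expect_equal(as.numeric(ddm_loglik(p, one)),
               ddm_fpt_density(one$rt_seconds,
                               ifelse(one$response == "high",
                                      "upper", "lower"),
                               p, v1, log = TRUE))
  # additivity under duplication
  expect_equal(as.numeric(ddm_loglik(p, rbind(rec, rec))),
               2 * as.numeric(ddm_loglik(p, rec)))
  # independent per-record loop oracle
  want <- sum(vapply(seq_len(nrow(rec)), function(i) {
    v <- p$beta_m * rec$delta_m[i] + p$beta_s * rec$delta_s[i]
    log(ref_fpt(rec$rt_seconds[i], rec$response[i] == "high", v, p$a,
                p$z, p$t0))
  }, 0))
  expect_equal(as.numeric(ddm_loglik(p, rec)), want, tolerance = 1e-8)
  # RT at or below t0 contributes -Inf and is reported
  rec2 <- rec
  rec2$rt_seconds[1] <- p$t0 - 0.01
  ll2 <- ddm_loglik(p, rec2)
  expect_identical(as.numeric(ll2), -Inf)
  expect_identical(attr(ll2, "n_invalid"), 1L)
})

test_that("simulated responses respect t0, the window, and extreme drift", {
  p <- ddm_params(a = 1.5, t0 = 0.4, beta_m = 1, beta_s = 0)
  sim <- simulate_ddm_paths(1000, p, v = 50, seed = 2)
  expect_gte(mean(sim$response == "high"), 0.99)
  expect_true(all(sim$rt_seconds > p$t0))
  expect_true(all(sim$rt_seconds <= 6))
})

test_that("simulated choice frequencies match the analytic probability", {
  set.seed(31)
  for (i in 1:5) {
    p <- ddm_params(a = runif(1, 0.8, 2.4), t0 = 0.3, beta_m = 0,
                    beta_s = 0, z = runif(1, 0.3, 0.7))
    v <- runif(1, -1.5, 1.5)
    n <- 40000
    sim <- simulate_ddm_paths(n, p, v, dt = 0.004, window = Inf)
    pa <- choice_probability(p, v)
    se <- sqrt(pa * (1 - pa) / n)
    expect_lt(abs(mean(sim$response == "high") - pa), 4 * se)
  }
})

test_that("a maximum-likelihood refit of simulated data recovers the
           generating parameters within 5%", {
  set.seed(12)
  trials <- data.frame(delta_m = runif(10000, 0.5, 15),
                       delta_s = sample(1:20, 10000, replace = TRUE))
  truth <- ddm_params(a = 1.8, t0 = 0.4, beta_m = 0.3, beta_s = -0.12)
  rec <- cbind(trials, simulate_ddm_trials(truth, trials, seed = 3))
  nll <- function(par) {
    p <- tryCatch(ddm_params(par[1], par[2], par[3], par[4]),
                  error = function(e) NULL)
    if (is.null(p)) return(1e10)
    -as.numeric(ddm_loglik(p, rec))
  }
  fit <- optim(c(1.4, 0.3, 0.1, -0.05), nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  est <- fit$par
  truth_vec <- c(truth$a, truth$t0, truth$beta_m, truth$beta_s)
  expect_true(all(abs(est - truth_vec) / abs(truth_vec) < 0.05))
})
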