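test_that("anticipatory-RT exclusion removes exactly the fast trials", {
  rec <- data.frame(participant_id = rep(c("s1", "s2"), each = 5),
                    rt_seconds = c(0.15, 0.5, 0.8, 0.19, 1.2,
                                   0.25, 0.3, 0.150, 2.0, 0.9))
  out <- preprocess_choices(rec)
  expect_equal(nrow(out), 7)
  expect_true(all(out$rt_seconds >= 0.2))
  rep1 <- attr(out, "exclusions")
  expect_equal(rep1$n_excluded[rep1$participant_id == "s1"], 2L)
  expect_equal(rep1$n_excluded[rep1$participant_id == "s2"], 1L)
  # idempotence (the exclusion report changes, the records do not)
  out2 <- preprocess_choices(out)
  expect_equal(out2, out, ignore_attr = TRUE)
  expect_true(all(attr(out2, "exclusions")$n_excluded == 0L))
  # no-op when all RTs are slow enough
  slow <- rec[rec$rt_seconds >= 0.2, ]
  expect_equal(preprocess_choices(slow), slow, ignore_attr = TRUE)
  # losing every trial warns
  fast <- data.frame(participant_id = "s1", rt_seconds = c(0.1, 0.12))
  expect_warning(preprocess_choices(fast), "no retained")
})

test_that("model bookkeeping: parameter labels follow the specification", {
  study <- tiny_study(n_subjects = 3, n_trials = 10)
  pr <- ddm_priors()
  m_naive <- build_hddm(ddm_model_spec("naive"), study$records, pr)
  expect_equal(nrow(m_naive$param_table), 4) # a, t0, bm, bs
  m_pd <- build_hddm(ddm_model_spec("prosocial_default"), study$records, pr)
  expect_setequal(m_pd$param_table$par,
                  c("a", "t0", "z_dirty", "z_clean", "bm", "bs"))
  m_vc <- build_hddm(ddm_model_spec("valuation_conflict"), study$records, pr)
  expect_setequal(m_vc$param_table$par,
                  c("a", "t0", "bm_dirty", "bm_clean",
                    "bs_dirty", "bs_clean"))
  m_hy <- build_hddm(ddm_model_spec("hybrid"), study$records, pr)
  expect_equal(nrow(m_hy$param_table), 8)
  # a factor absent from the data is a configuration error
  spec2 <- ddm_model_spec("valuation_conflict",
                          factors = c("source", "destination"))
  expect_error(build_hddm(spec2, study$records, pr), "configuration error")
})

test_that("sampling is deterministic given the seed and respects the priors", {
  study <- tiny_study(n_subjects = 3, n_trials = 12)
  spec <- ddm_model_spec("naive")
  f1 <- ddm_fit(study$records, spec, n_iter = 150, n_burn = 50,
                n_chains = 2, seed = 9)
  f2 <- ddm_fit(study$records, spec, n_iter = 150, n_burn = 50,
                n_chains = 2, seed = 9)
  expect_identical(f1$posterior$chains, f2$posterior$chains)
  # every draw inside its stated uniform interval
  draws <- as.matrix(f1)
  pt <- f1$posterior$param_table
  for (k in seq_len(nrow(pt))) {
    mu <- draws[, paste0("mu_", pt$par[k])]
    expect_true(all(mu >= pt$lo[k] & mu <= pt$hi[k]))
    sub <- draws[, grep(paste0("^", pt$par[k], "\\["), colnames(draws))]
    expect_true(all(sub >= pt$lo[k] & sub <= pt$hi[k]))
  }
})

test_that("with a constant likelihood the group locations recover their
           uniform priors", {
  study <- tiny_study(n_subjects = 2, n_trials = 5)
  model <- build_hddm(ddm_model_spec("naive"), study$records, ddm_priors())
  post <- sample_hddm(model, n_iter = 6000, n_burn = 500, n_chains = 1,
                      seed = 4, use_likelihood = FALSE)
  draws <- post$chains[[1]]
  # U(0.3, 6) boundary prior: mean 3.15; U(-3, 3) weight priors: mean 0
  expect_lt(abs(mean(draws[, "mu_a"]) - 3.15), 0.35)
  expect_lt(abs(mean(draws[, "mu_bm"]) - 0), 0.4)
  expect_lt(abs(mean(draws[, "mu_t0"]) - 0.775), 0.12)
})

test_that("group-location posteriors recover known generating values", {
  cfg <- population_config(
    "study1", n_subjects = 12, n_trials = 60,
    spec = ddm_model_spec("vc_money"),
    group_mean = list(bm = c(dirty = 0.28, clean = 0.35), bs = -0.12))
  study <- generate_choice_study(cfg, seed = 21)
  fit <- ddm_fit(study$records, ddm_model_spec("vc_money"),
                 n_iter = 1500, n_burn = 500, n_chains = 1, seed = 22)
  draws <- as.matrix(fit)
  truth <- c(a = 1.8, t0 = 0.4, bm_dirty = 0.28, bm_clean = 0.35,
             bs = -0.12)
  for (p in names(truth)) {
    ci <- quantile(draws[, paste0("mu_", p)], c(0.025, 0.975))
    expect_gte(truth[[p]], ci[[1]])
    expect_lte(truth[[p]], ci[[2]])
  }
})

test_that("a sparsely observed subject shrinks further towards the group
           mean than a densely observed one", {
  set.seed(55)
  trials <- generate_trial_set(100, "study1", seed = 56)
  group <- ddm_params(a = 1.8, t0 = 0.4, beta_m = 0.30, beta_s = -0.12)
  outlier <- ddm_params(a = 1.8, t0 = 0.4, beta_m = 0.55, beta_s = -0.12)
  mk <- function(id, p, n) {
    tr <- trials[seq_len(n), ]
    cbind(participant_id = id, tr[c("delta_m", "delta_s")],
          simulate_ddm_trials(p, tr))
  }
  rec <- rbind(
    do.call(rbind, lapply(1:6, function(i)
      mk(paste0("g", i), group, 100))),
    mk("sparse", outlier, 10), mk("dense", outlier, 100))
  fit <- ddm_fit(rec, ddm_model_spec("naive"), n_iter = 1200, n_burn = 400,
                 n_chains = 1, seed = 57)
  draws <- as.matrix(fit)
  mu <- mean(draws[, "mu_bm"])
  d_sparse <- abs(mean(draws[, "bm[sparse]"]) - mu)
  d_dense <- abs(mean(draws[, "bm[dense]"]) - mu)
  expect_lt(d_sparse, d_dense)
})

test_that("Gelman-Rubin statistic matches the textbook formula and flags
           separated runs", {
  set.seed(8)
  runs <- lapply(1:3, function(i)
    cbind(theta = rnorm(200, 0, 1), eta = rnorm(200, 5, 2)))
  got <- gelman_rubin(runs)
  expect_equal(got[["theta"]], ref_psrf(lapply(runs, function(r) r[, 1])),
               tolerance = 1e-10)
  expect_equal(got[["eta"]], ref_psrf(lapply(runs, function(r) r[, 2])),
               tolerance = 1e-10)
  # two identical runs: between-run variance 0, R = sqrt((n-1)/n) ~ 1
  r1 <- cbind(theta = rnorm(100))
  expect_equal(unname(gelman_rubin(list(r1, r1))), 1, tolerance = 0.01)
  # far-separated runs
  far <- list(cbind(theta = rnorm(200, 0)), cbind(theta = rnorm(200, 10)))
  expect_gt(gelman_rubin(far)[["theta"]], 1.1)
  expect_error(gelman_rubin(list(r1)), "at least two")
})
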