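test_that("joint log density is the sum of trial likelihoods and priors", {
  coh <- small_cohort(n = 2, conditions = c(9L, 11L), tpv = 5, seed = 2)
  f <- filter_trials(coh$trials, expected_per_participant = 10)
  dat <- csddm:::csddm_data(f$retained)
  spec <- quick_spec()
  set.seed(1)
  theta <- rbind(runif(dat$ncell, 0.5, 1.5), runif(dat$ncell, -0.3, 0.3),
                 runif(dat$ncell, 0, 0.5),
                 runif(dat$ncell, 0.05, 0.9) * dat$minrt)
  mu <- matrix(c(1, 0, 0.3, 0.3), 4, length(dat$conds))
  sig <- matrix(0.4, 4, length(dat$conds))
  got <- csddm:::csddm_joint_logdensity(dat, theta, mu, sig, spec)

  # independent reimplementation, trial by trial, through the public density
  ll <- 0
  for (i in seq_len(dat$n_trials)) {
    ce <- dat$cell[i]
    p <- ddm_params(dat$sign[i] * theta[1, ce], exp(theta[3, ce]),
                    plogis(theta[2, ce]), theta[4, ce])
    ll <- ll + wfpt_logdensity(dat$rt[i], dat$upper[i] == 1, p, eps = spec$eps)
  }
  cc <- dat$cellcond
  for (p in 1:4)
    ll <- ll + sum(dnorm(theta[p, ], mu[p, cc], sig[p, cc], log = TRUE))
  pr <- spec$priors
  ll <- ll + sum(dnorm(mu[1, ], pr$mu_drift[1], pr$mu_drift[2], log = TRUE)) +
    sum(dnorm(mu[2, ], pr$mu_bias[1], pr$mu_bias[2], log = TRUE)) +
    sum(dnorm(mu[3, ], pr$mu_boundary[1], pr$mu_boundary[2], log = TRUE)) +
    sum(dnorm(mu[4, ], pr$mu_ndt[1], pr$mu_ndt[2], log = TRUE)) +
    sum(dnorm(sig, 0, pr$sd_scale, log = TRUE))
  expect_equal(got, ll, tolerance = 1e-8)
})

test_that("stimulus coding negates drift on same trials", {
  # a same-truth trial answered "different" is an upper-boundary crossing
  # under negated drift, i.e. the reflected lower-boundary density
  rec <- make_records(rt_ms = 900, truth = "same", response = "different")
  dat <- csddm:::csddm_data(rec)
  expect_identical(dat$sign, -1)
  expect_identical(dat$upper, 1L)
  v <- 1.2; a <- 1.5; w <- 0.45; tau <- 0.3
  got <- csddm:::wfpt_loglik_cells_cpp(dat$rt, dat$upper, dat$cell, dat$sign,
                                       v, a, w, tau, 1L, 1e-10)
  expect_equal(got,
               wfpt_logdensity(0.9, "upper", ddm_params(-v, a, w, tau)))
  expect_equal(got,
               wfpt_logdensity(0.9, "lower", ddm_params(v, a, 1 - w, tau)))
})

test_that("model spec validation and data preconditions", {
  expect_error(csddm_spec(draws = 0))
  expect_error(csddm_spec(priors = list(mu_drift = c(0, -1),
                                        mu_bias = c(0, 1), mu_boundary = c(0, 1),
                                        mu_ndt = c(0.3, 0.3), sd_scale = 1)),
               "prior scales")
  expect_error(fit_csddm(make_records(rt_ms = numeric(0))[0, ], quick_spec()),
               "empty")
  bad <- make_records(rt_ms = c(500, 0))
  expect_error(fit_csddm(bad, quick_spec()), "positive")
})

test_that("dominating priors pin the posterior to their centers", {
  coh <- small_cohort(n = 4, conditions = 9L, tpv = 10, seed = 8)
  f <- filter_trials(coh$trials, expected_per_participant = 10)
  centers <- list(mu_drift = c(1.1, 1e-3), mu_bias = c(0.2, 1e-3),
                  mu_boundary = c(0.6, 1e-3), mu_ndt = c(0.25, 1e-3),
                  sd_scale = 0.05)
  fit <- suppressWarnings(fit_csddm(f$retained,
    quick_spec(chains = 2, warmup = 250, draws = 250, seed = 3,
               priors = centers)))
  est <- apply(fit$draws$mu, 2, mean)
  expect_equal(unname(est),
               c(1.1, 0.2, 0.6, 0.25), tolerance = 0.02)
})

test_that("identical seeds give identical fits", {
  coh <- small_cohort(n = 3, conditions = 9L, tpv = 15, seed = 14)
  f <- filter_trials(coh$trials, expected_per_participant = 15)
  fit1 <- suppressWarnings(fit_csddm(f$retained,
    quick_spec(chains = 2, warmup = 150, draws = 150, seed = 5)))
  fit2 <- suppressWarnings(fit_csddm(f$retained,
    quick_spec(chains = 2, warmup = 150, draws = 150, seed = 5)))
  expect_identical(fit1$draws$mu, fit2$draws$mu)
  expect_identical(fit1$draws$theta, fit2$draws$theta)
})

test_that("zero between-person variance concentrates the group SD near 0", {
  coh <- generate_cohort(cohort_config(
    n_participants = 24, conditions = 9L, trials_per_version = 120,
    group_sds = c(drift = 0, bias_logit = 0, boundary_log = 0, ndt = 0),
    session_missing_prob = 0, contaminant_rate = 0, seed = 17))
  f <- filter_trials(coh$trials, expected_per_participant = 120)
  fit <- suppressWarnings(fit_csddm(f$retained,
    quick_spec(chains = 2, warmup = 600, draws = 600, seed = 2)))
  for (p in 1:4)
    expect_gt(mean(fit$draws$sig[, p, 1] < 0.1), 0.8)
})

test_that("contrasts are per-draw marginal differences with exact antisymmetry", {
  fx <- shared_small_fit()
  fit <- fx$fit
  ctr <- contrasts_csddm(fit)
  # recompute the bias contrast by hand from the mu draws
  man <- marginal_group_draws(fit, "bias_logit",
    list(probe_type = "single_probe", change_prob = "high_80"))
  base <- marginal_group_draws(fit, "bias_logit",
    list(probe_type = "single_probe", change_prob = "low_50"))
  d <- man - base
  row <- ctr[ctr$parameter == "bias_logit", ]
  expect_equal(row$mean, mean(d), tolerance = 1e-12)
  expect_equal(row$ci_low, unname(quantile(d, 0.025)), tolerance = 1e-12)
  # relabelling manipulated/baseline flips the draws exactly
  expect_equal(base - man, -d)
  # back-transformed scales stay in their domains for every draw
  expect_true(all(plogis(fit$draws$mu[, 2, ]) > 0 &
                    plogis(fit$draws$mu[, 2, ]) < 1))
  expect_true(all(exp(fit$draws$mu[, 3, ]) > 0))
})

test_that("condition summaries marginalise over non-focal factors per draw", {
  fx <- shared_small_fit()
  fit <- fx$fit
  sm <- condition_summaries(fit)
  # the drift summary at short study averages all 4 fitted conditions
  d <- marginal_group_draws(fit, "drift",
    list(probe_type = "single_probe", study_time = "short_500ms"))
  expect_equal(d, rowMeans(fit$draws$mu[, 1, ]), tolerance = 1e-12)
  row <- sm[sm$parameter == "drift" & sm$level == "short_500ms", ]
  expect_equal(row$mean, mean(d), tolerance = 1e-12)
  # constant draws summarise with zero width
  ps <- csddm:::posterior_summary(rep(1.5, 100))
  expect_identical(ps$sd, 0)
  expect_identical(ps$ci_low, ps$mean)
  expect_identical(ps$ci_high, ps$mean)
})

test_that("convergence diagnostics flag trending chains and pass white noise", {
  set.seed(3)
  chain <- rep(1:2, each = 500)
  expect_lt(csddm:::split_rhat(rnorm(1000), chain), 1.01)
  trending <- c(rnorm(500), rnorm(500) + 1.5)
  expect_gt(csddm:::split_rhat(trending, chain), 1.1)
  expect_gt(csddm:::ess_geyer(rnorm(1000), chain), 500)
})
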