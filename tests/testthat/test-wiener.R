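test_that("parameter domain is enforced and pre-decision times carry no mass", {
  expect_error(ddm_params(1, -1, 0.5, 0.3), "boundary")
  expect_error(ddm_params(1, 0, 0.5, 0.3), "boundary")
  expect_error(ddm_params(1, 1, 0, 0.3), "bias")
  expect_error(ddm_params(1, 1, 1.2, 0.3), "bias")
  expect_error(ddm_params(1, 1, 0.5, -0.1), "ndt")
  p <- ddm_params(1, 1, 0.5, 0.3)
  # t <= ndt is log(0), not an error: cleaning belongs to preprocessing
  expect_identical(wfpt_logdensity(0.3, "upper", p), -Inf)
  expect_identical(wfpt_logdensity(0.1, "lower", p), -Inf)
  expect_true(is.finite(wfpt_logdensity(0.31, "upper", p)))
})

test_that("driftless symmetric process has equal boundary densities", {
  p <- ddm_params(0, 1, 0.5, 0)
  tt <- seq(0.05, 4, by = 0.05)
  expect_equal(wfpt_logdensity(tt, rep(TRUE, length(tt)), p),
               wfpt_logdensity(tt, rep(FALSE, length(tt)), p))
})

test_that("reflection maps the upper density onto the lower exactly", {
  set.seed(4)
  for (i in 1:10) {
    v <- runif(1, -3, 3); a <- runif(1, 0.5, 3); w <- runif(1, 0.1, 0.9)
    tt <- runif(5, 0.05, 3)
    up <- wfpt_logdensity(tt, rep(TRUE, 5), ddm_params(v, a, w, 0))
    lo <- wfpt_logdensity(tt, rep(FALSE, 5), ddm_params(-v, a, 1 - w, 0))
    expect_identical(up, lo)
  }
})

test_that("series density matches an independent long-truncation evaluation", {
  # independent oracle: plain 2000-term large-time series with the
  # reflection written out by hand
  slow_upper <- function(t, v, a, w, ndt) {
    td <- t - ndt; vv <- -v; ww <- 1 - w
    tau <- td / a^2
    k <- 1:2000
    f <- pi * sum(k * exp(-k^2 * pi^2 * tau / 2) * sin(k * pi * ww))
    log(f) - vv * a * ww - vv^2 * td / 2 - 2 * log(a)
  }
  p <- ddm_params(1, 1, 0.5, 0.3)
  expect_equal(wfpt_logdensity(0.8, "upper", p), -1.072671222449,
               tolerance = 1e-8)
  set.seed(7)
  for (i in 1:12) {
    v <- runif(1, -2, 2); a <- runif(1, 0.6, 2.5); w <- runif(1, 0.15, 0.85)
    t <- runif(1, 0.4, 3)
    expect_equal(wfpt_logdensity(t, "upper", ddm_params(v, a, w, 0)),
                 slow_upper(t, v, a, w, 0), tolerance = 1e-8)
  }
})

test_that("density normalises and its upper mass matches the closed form", {
  set.seed(21)
  for (i in 1:8) {
    p <- ddm_params(runif(1, -3, 3), runif(1, 0.5, 3), runif(1, 0.1, 0.9), 0.2)
    iu <- integrate(function(t) exp(wfpt_logdensity(t, rep(TRUE, length(t)), p)),
                    0.2, Inf, rel.tol = 1e-9)$value
    il <- integrate(function(t) exp(wfpt_logdensity(t, rep(FALSE, length(t)), p)),
                    0.2, Inf, rel.tol = 1e-9)$value
    expect_lt(abs(iu + il - 1), 1e-4)
    expect_lt(abs(iu - prob_upper(p)), 1e-4)
  }
})

test_that("absorption probability: driftless cases and monotonicity", {
  expect_equal(prob_upper(ddm_params(0, 1, 0.5, 0)), 0.5)
  expect_equal(prob_upper(ddm_params(0, 1, 0.8, 0)), 0.8)
  expect_equal(prob_upper(ddm_params(1, 1, 0.5, 0)), 0.7310585786,
               tolerance = 1e-8)
  drifts <- seq(-3, 3, by = 0.25)
  pu <- vapply(drifts, function(v) prob_upper(ddm_params(v, 1.5, 0.4, 0)), 0)
  expect_true(all(diff(pu) > 0))
  biases <- seq(0.05, 0.95, by = 0.05)
  pb <- vapply(biases, function(w) prob_upper(ddm_params(0.7, 1.5, w, 0)), 0)
  expect_true(all(diff(pb) > 0))
})

test_that("exact sampler honours the seed contract and edge cases", {
  p <- ddm_params(1, 1, 0.5, 0.3)
  expect_identical(nrow(sample_trials(p, 0)), 0L)
  s1 <- sample_trials(p, 50, seed = 5)
  s2 <- sample_trials(p, 50, seed = 5)
  expect_identical(s1, s2)
  expect_true(all(s1$rt > p$ndt))
})

test_that("sampled choices and RTs agree with the density", {
  p <- ddm_params(1, 1, 0.5, 0.3)
  n <- 2e4
  s <- sample_trials(p, n, seed = 8)
  pu <- prob_upper(p)
  expect_lt(abs(mean(s$choice == "upper") - pu), 3 * sqrt(pu * (1 - pu) / n))
  # KS distance of upper-choice RTs against the numerically integrated CDF
  tt <- seq(1e-4, 30, length.out = 2^15)
  dens <- exp(wfpt_logdensity(tt + p$ndt, rep(TRUE, length(tt)), p))
  cdf <- cumsum(c(0, diff(tt) * (dens[-1] + dens[-length(tt)]) / 2))
  cdf <- cdf / pu
  x <- sort(s$rt[s$choice == "upper"] - p$ndt)
  Fx <- approx(tt, cdf, xout = x, rule = 2)$y
  m <- length(x)
  ks <- max(pmax(abs(Fx - (seq_len(m) - 1) / m), abs(Fx - seq_len(m) / m)))
  expect_lt(ks, 0.01)
})

test_that("exact sampler agrees with the discretised reference simulator", {
  # Euler-Maruyama is an independent code path; its sqrt(dt) discretisation
  # bias bounds how tight this cross-check can be
  p <- ddm_params(1, 1, 0.5, 0.3)
  ex <- sample_trials(p, 2e4, seed = 31)
  em <- sample_trials_em(p, 2e4, seed = 32, dt = 1e-4)
  expect_lt(abs(mean(ex$choice == "upper") - mean(em$choice == "upper")), 0.015)
  ks <- suppressWarnings(stats::ks.test(ex$rt[ex$choice == "upper"],
                                        em$rt[em$choice == "upper"]))
  expect_lt(unname(ks$statistic), 0.03)
  # joint density mass near the frozen reference point
  mass_exact <- integrate(function(t)
    exp(wfpt_logdensity(t, rep(TRUE, length(t)), p)), 0.75, 0.85,
    rel.tol = 1e-9)$value
  mass_em <- mean(em$choice == "upper" & em$rt > 0.75 & em$rt <= 0.85)
  expect_lt(abs(mass_em - mass_exact), 0.008)
})
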