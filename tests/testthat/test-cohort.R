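test_that("version schedules are complete and drawn from 3 orderings", {
  expect_identical(nrow(make_schedule(0, 1)), 0L)
  sch <- make_schedule(30, 3)
  for (i in unique(sch$participant)) {
    si <- sch[sch$participant == i, ]
    expect_identical(sort(si$version), 1:16)       # every version once
    expect_identical(si$day, rep(1:8, each = 2L))  # 2 per day over 8 days
  }
  orders <- vapply(split(sch$version, sch$participant), paste, "",
                   collapse = ",")
  expect_lte(length(unique(orders)), 3L)
  expect_identical(make_schedule(30, 3), sch)      # seed contract
})

test_that("trial truth composition is exact per change-probability level", {
  hi <- trial_truths(condition_table()[11, ], 5)   # high_80 version
  expect_identical(sum(hi == "different"), 48L)
  expect_identical(sum(hi == "same"), 12L)
  lo <- trial_truths(condition_table()[9, ], 5)    # low_50 version
  expect_identical(sum(lo == "different"), 30L)
  expect_identical(trial_truths(9, 5), lo)         # seed contract, index form
})

test_that("cohort config rejects invalid settings", {
  expect_error(cohort_config(n_participants = -1), "n_participants")
  expect_error(cohort_config(group_sds = c(drift = -1, bias_logit = 0.2,
                                           boundary_log = 0.2, ndt = 0.05)),
               "SDs")
  expect_error(cohort_config(session_missing_prob = 1.5), "rates")
  expect_error(cohort_config(age_drift_cor = -2), "age_drift_cor")
})

test_that("clean cohorts contain every scheduled trial with a response", {
  expect_identical(nrow(generate_cohort(cohort_config(0))$trials), 0L)
  coh <- generate_cohort(cohort_config(
    n_participants = 3, conditions = c(9L, 11L), trials_per_version = 15,
    session_missing_prob = 0, contaminant_rate = 0,
    record_deadline_trials = TRUE, seed = 2))
  expect_identical(nrow(coh$trials), 3L * 2L * 15L)
  expect_true(all(coh$trials$response %in% c("same", "different")))
  expect_true(all(coh$trials$rt_ms > 0))
  # reproducibility of data and ground truth jointly
  coh2 <- generate_cohort(cohort_config(
    n_participants = 3, conditions = c(9L, 11L), trials_per_version = 15,
    session_missing_prob = 0, contaminant_rate = 0,
    record_deadline_trials = TRUE, seed = 2))
  expect_identical(coh$trials, coh2$trials)
  expect_identical(coh$truth$person_params, coh2$truth$person_params)
})

test_that("zero between-person SDs collapse the hierarchy", {
  coh <- generate_cohort(cohort_config(
    n_participants = 4, conditions = sp_conditions, trials_per_version = 2,
    group_sds = c(drift = 0, bias_logit = 0, boundary_log = 0, ndt = 0),
    session_missing_prob = 0, contaminant_rate = 0, seed = 6))
  pp <- coh$truth$person_params
  for (v in sp_conditions) {
    pv <- pp[pp$version == v, ]
    for (col in c("drift", "bias_logit", "boundary_log", "ndt"))
      expect_identical(length(unique(pv[[col]])), 1L)
  }
})

test_that("planted contaminants are recovered exactly by the RT filter", {
  coh <- generate_cohort(cohort_config(
    n_participants = 6, conditions = c(9L, 11L), trials_per_version = 30,
    session_missing_prob = 0, contaminant_rate = 0.05,
    record_deadline_trials = TRUE, seed = 13))
  planted <- length(coh$planted$contaminant_rows)
  expect_gt(planted, 0)
  f <- filter_trials(coh$trials, expected_per_participant = 60)
  expect_identical(unname(f$report$counts[["rt_bound_excluded"]]), planted)
})

test_that("session missingness hits the configured unrecorded rate", {
  rates <- vapply(1:10, function(s) {
    coh <- generate_cohort(cohort_config(
      n_participants = 68, trials_per_version = 1, contaminant_rate = 0,
      record_deadline_trials = TRUE, seed = 100 + s))
    1 - nrow(coh$trials) / (68 * 16)
  }, 0)
  expect_lt(abs(mean(rates) - 0.0845), 0.01)
})

test_that("ground-truth age-drift correlation tracks the configured target", {
  cors <- vapply(1:3, function(s) {
    coh <- generate_cohort(cohort_config(
      n_participants = 68, trials_per_version = 1, contaminant_rate = 0,
      session_missing_prob = 0, record_deadline_trials = TRUE,
      seed = 200 + s))
    pp <- coh$truth$person_params
    pd <- tapply(pp$drift, pp$participant, mean)
    cor(coh$truth$ages, as.numeric(pd))
  }, 0)
  expect_true(all(abs(cors - (-0.45)) < 0.1))
})

test_that("trial tables round-trip through CSV", {
  coh <- small_cohort(n = 2, tpv = 5, seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trials_csv(coh$trials, path)
  back <- read_trials_csv(path)
  expect_equal(back$rt_ms, coh$trials$rt_ms, tolerance = 1e-8)
  expect_identical(back$response, coh$trials$response)
  expect_identical(back$version_index, coh$trials$version_index)
})
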