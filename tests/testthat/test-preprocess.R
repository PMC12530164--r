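test_that("RT bounds are strict: 200 and 7000 ms exactly are retained", {
  rec <- make_records(rt_ms = c(150, 200, 250, 7000, 7500, 900, 1100, 1300,
                                2000, 2500))
  f <- filter_trials(rec, expected_per_participant = 10)
  expect_identical(unname(f$report$counts[["rt_bound_excluded"]]), 2L)
  expect_identical(nrow(f$retained), 8L)
  expect_true(all(c(200, 7000) %in% f$retained$rt_ms))
  expect_false(any(c(150, 7500) %in% f$retained$rt_ms))
})

test_that("trial accounting identities hold and percentages recompute", {
  coh <- generate_cohort(cohort_config(
    n_participants = 10, conditions = sp_conditions, trials_per_version = 30,
    session_missing_prob = 0.1, contaminant_rate = 0.02, seed = 4))
  f <- filter_trials(coh$trials, expected_per_participant = 120)
  k <- f$report$counts
  expect_identical(k[["scheduled"]], k[["recorded"]] + k[["unrecorded"]])
  expect_identical(k[["retained"]],
                   k[["recorded"]] - k[["deadline_excluded"]] -
                     k[["rt_bound_excluded"]])
  expect_true(all(k >= 0))
  expect_equal(unname(f$report$rates),
               unname(round(100 * k / k[["scheduled"]], 2)))
  # deadline-censored trials are the unresponded rows, not double-counted
  expect_identical(unname(k[["deadline_excluded"]]),
                   sum(coh$trials$response == "none"))
})

test_that("filtering is idempotent", {
  coh <- generate_cohort(cohort_config(
    n_participants = 5, conditions = sp_conditions, trials_per_version = 20,
    session_missing_prob = 0.1, contaminant_rate = 0.05, seed = 9))
  f1 <- filter_trials(coh$trials, expected_per_participant = 80)
  f2 <- filter_trials(f1$retained, expected_per_participant = 80)
  expect_identical(f2$retained, f1$retained)
  expect_identical(unname(f2$report$counts[["deadline_excluded"]]), 0L)
  expect_identical(unname(f2$report$counts[["rt_bound_excluded"]]), 0L)
})

test_that("malformed RTs are rejected", {
  rec <- make_records(rt_ms = c(500, -10))
  expect_error(filter_trials(rec, 2), "malformed")
})

test_that("accuracy is correct-over-total with both probe types reported", {
  rec <- rbind(
    make_records(version = 9, rt_ms = rep(1000, 7), truth = "different",
                 response = "different"),
    make_records(version = 1, rt_ms = rep(1200, 4),
                 truth = c("same", "same", "different", "different"),
                 response = c("same", "different", "different", "same")))
  out <- accuracy_summary(rec)
  expect_equal(out$accuracy_pct[out$probe_type == "Overall"],
               round(100 * 9 / 11, 2))
  expect_equal(out$accuracy_pct[out$probe_type == "single_probe"], 100)
  expect_equal(out$accuracy_pct[out$probe_type == "whole_display"], 50)
  expect_equal(out$mean_rt_ms[out$probe_type == "Overall"],
               round(mean(rec$rt_ms), 2))
  expect_identical(nrow(accuracy_summary(rec[0, ])), 0L)
})

test_that("engagement distribution reproduces planted missingness", {
  full <- do.call(rbind, lapply(1:16, function(v)
    make_records(participant = 1L, version = v, rt_ms = rep(1000, 60))))
  partial <- do.call(rbind, lapply(1:4, function(v)
    make_records(participant = 2L, version = v, rt_ms = rep(1000, 60))))
  eng <- engagement_summary(rbind(full, partial), 960)
  per <- eng$per_participant
  expect_equal(per$completion_pct[per$participant_id == 1], 100.0)
  expect_identical(per$versions_completed[per$participant_id == 1], 16L)
  expect_equal(per$completion_pct[per$participant_id == 2], 25.0)
  expect_identical(per$trials_completed[per$participant_id == 2], 240L)
  expect_identical(per$versions_completed[per$participant_id == 2], 4L)
  # distribution rows: one per completion level with participant counts
  expect_identical(sum(eng$distribution$participants), 2L)
})

test_that("engagement histogram matches sessions planted by the generator", {
  coh <- generate_cohort(cohort_config(
    n_participants = 12, trials_per_version = 2, session_missing_prob = 0.2,
    contaminant_rate = 0, record_deadline_trials = TRUE, seed = 21))
  eng <- engagement_summary(coh$trials, 32)
  dropped <- coh$planted$dropped_sessions
  for (i in unique(coh$trials$participant_id)) {
    expected_versions <- 16L - sum(dropped$participant == i)
    expect_identical(
      eng$per_participant$versions_completed[
        eng$per_participant$participant_id == i], expected_versions)
  }
})
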