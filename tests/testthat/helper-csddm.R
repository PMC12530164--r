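# Shared fixtures and small helpers for the test suite.  Everything is
# generated in code; no stored data.

# single-probe versions crossing change probability x urgency at short study
sp_conditions <- c(9L, 11L, 13L, 15L)

quick_spec <- function(chains = 2, warmup = 300, draws = 300, seed = 1, ...) {
  csddm_spec(chains = chains, warmup = warmup, draws = draws, seed = seed, ...)
}

# a small clean cohort (no missingness/contaminants/censoring surprises)
small_cohort <- function(n = 6, conditions = sp_conditions, tpv = 20, seed = 1,
                         ...) {
  generate_cohort(cohort_config(
    n_participants = n, conditions = conditions, trials_per_version = tpv,
    session_missing_prob = 0, contaminant_rate = 0, seed = seed, ...))
}

# hand-built trial records with full control over every field
make_records <- function(participant = 1L, version = 9L, rt_ms,
                         truth = "different", response = "different",
                         day = 1L) {
  n <- max(length(rt_ms), length(truth), length(response))
  cond <- condition_table()[version, ]
  data.frame(
    participant_id = rep_len(participant, n), age = 50,
    day = day, version_index = cond$version,
    study_time_ms = cond$study_ms, change_prob = cond$change_prob,
    deadline_ms = cond$deadline_ms, probe_type = cond$probe_type,
    trial_index = seq_len(n), truth = rep_len(truth, n),
    response = rep_len(response, n), rt_ms = rep_len(rt_ms, n),
    stringsAsFactors = FALSE)
}

# one shared small fit, computed lazily and reused across test files
.fixture_env <- new.env(parent = emptyenv())
shared_small_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    coh <- small_cohort(n = 6, tpv = 20, seed = 11)
    f <- filter_trials(coh$trials, expected_per_participant = 4 * 20)
    .fixture_env$cohort <- coh
    .fixture_env$retained <- f$retained
    .fixture_env$fit <- suppressWarnings(
      fit_csddm(f$retained, quick_spec(chains = 2, warmup = 250, draws = 250,
                                       seed = 77)))
  }
  .fixture_env
}
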