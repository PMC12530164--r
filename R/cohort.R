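#' Default group-level parameter means per task version
#'
#' Ground-truth group means on the sampling scales (drift natural, bias
#' logit, boundary log, nondecision time in seconds), set to magnitudes
#' typical of fitted condition summaries for this task family:
#' drift depends on study time and probe type, logit bias on change
#' probability and probe type, log boundary on urgency and probe type, and
#' nondecision time is constant.  Used as the default truth of
#' [cohort_config()] so that recovery experiments exercise realistic effect
#' sizes.
#'
#' @param conditions Version indices to include (default all 16).
#' @return A data.frame with `version`, the factor columns and the four
#'   parameter-mean columns `drift`, `bias_logit`, `boundary_log`, `ndt`.
#' @export
default_group_means <- function(conditions = 1:16) {
  tab <- condition_table()[conditions, , drop = FALSE]
  wd <- tab$probe_type == "whole_display"
  tab$drift <- ifelse(tab$study_time == "short_500ms",
                      ifelse(wd, 1.65, 0.88),
                      ifelse(wd, 1.37, 0.90))
  tab$bias_logit <- ifelse(tab$change_prob == "low_50",
                           ifelse(wd, 0.07, -0.05),
                           ifelse(wd, 0.13, 0.10))
  tab$boundary_log <- ifelse(tab$urgency == "minimal_10000ms",
                             ifelse(wd, 0.92, 0.71),
                             ifelse(wd, 0.91, 0.66))
  tab$ndt <- 0.35
  tab[, c("version", condition_factors,
          "drift", "bias_logit", "boundary_log", "ndt")]
}

#' Configuration of a synthetic cohort
#'
#' Describes a complete synthetic study: sample size, ground-truth group
#' means and between-person SDs on the sampling scales, the age
#' distribution and its target correlation with drift, session-level
#' missingness, and contaminant response times.  Defaults emulate the
#' reference ambulatory study design: 68 participants, age mean 49 (SD 14, range 24-80),
#' age-drift correlation -0.45, ~8.45% of scheduled trials unrecorded
#' through whole-session missingness, and a small fraction of responded
#' trials replaced by implausibly fast or slow RTs.
#'
#' @param n_participants Number of participants.
#' @param conditions Task versions to schedule (default all 16; subsets are
#'   used for scaled-down recovery experiments, scheduled round-robin).
#' @param group_means Data.frame as returned by [default_group_means()].
#' @param group_sds Named vector of between-person SDs on the sampling
#'   scales for `drift`, `bias_logit`, `boundary_log`, `ndt`.
#' @param trials_per_version Trials per session (60 in the study).
#' @param age_mean,age_sd,age_range Age distribution (truncated normal).
#' @param age_drift_cor Target correlation between age and the person-level
#'   drift deviation (shared across conditions).
#' @param session_missing_prob Probability that a scheduled session
#'   (participant x version) goes entirely unrecorded.
#' @param trial_missing_prob Probability that an individual trial goes
#'   unrecorded (secondary knob, default 0).
#' @param contaminant_rate Fraction of responded trials whose RT is
#'   replaced by a contaminant draw.
#' @param contaminant_fast_ms,contaminant_slow_ms Uniform ranges (ms) for
#'   fast and slow contaminants (chosen with equal probability).
#' @param record_deadline_trials If `TRUE`, trials whose simulated RT
#'   exceeds the response window are recorded with the RT at the deadline
#'   instead of being marked unresponded (robustness-testing knob).
#' @param seed Integer seed governing the whole cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 68,
                          conditions = 1:16,
                          group_means = default_group_means(conditions),
                          group_sds = c(drift = 0.45, bias_logit = 0.22,
                                        boundary_log = 0.22, ndt = 0.07),
                          trials_per_version = 60L,
                          age_mean = 49, age_sd = 14, age_range = c(24, 80),
                          age_drift_cor = -0.45,
                          session_missing_prob = 0.0845,
                          trial_missing_prob = 0,
                          contaminant_rate = 0.0009,
                          contaminant_fast_ms = c(50, 199),
                          contaminant_slow_ms = c(7001, 12000),
                          record_deadline_trials = FALSE,
                          seed = 1L) {
  cfg <- as.list(environment())
  if (n_participants < 0) stop("n_participants must be >= 0", call. = FALSE)
  if (any(group_sds < 0)) stop("group SDs must be >= 0", call. = FALSE)
  for (r in c(session_missing_prob, trial_missing_prob, contaminant_rate))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]", call. = FALSE)
  if (abs(age_drift_cor) > 1) stop("age_drift_cor must be in [-1, 1]", call. = FALSE)
  need <- c("version", condition_factors, "drift", "bias_logit", "boundary_log", "ndt")
  if (!all(need %in% names(group_means)))
    stop("group_means is missing columns: ",
         paste(setdiff(need, names(group_means)), collapse = ", "), call. = FALSE)
  class(cfg) <- "cohort_config"
  cfg
}

rtruncnorm1 <- function(n, mean, sd, lo, hi) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
  }
  x
}

#' Generate a synthetic study cohort
#'
#' Draws ages and person-condition DDM parameters from the configured
#' group distributions, simulates every scheduled trial through the exact
#' first-passage sampler (drift sign set by trial truth: positive toward
#' "Different" on different trials, negated on same trials), applies
#' deadline censoring, whole-session missingness, and contaminant RTs, and
#' returns both the observed-data table and the generating ground truth.
#'
#' The person-level drift deviation is a linear-Gaussian function of
#' standardised age, shared across conditions, so the configured age-drift
#' correlation holds by construction; the other three parameters get
#' independent person-condition deviations.
#'
#' @param config A [cohort_config] object.
#' @return A list of class `csddm_cohort` with elements `trials` (the
#'   long-format trial table), `truth` (list: `person_params`, `ages`,
#'   `group_means`, `group_sds`) and `planted` (bookkeeping of dropped
#'   sessions and contaminated rows, for audit tests).
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  cfg <- config
  n <- cfg$n_participants
  gm <- cfg$group_means
  tab <- condition_table()
  empty <- data.frame(participant_id = integer(0), age = numeric(0),
                      day = integer(0), version_index = integer(0),
                      study_time_ms = integer(0), change_prob = character(0),
                      deadline_ms = integer(0), probe_type = character(0),
                      trial_index = integer(0), truth = character(0),
                      response = character(0), rt_ms = numeric(0))
  if (n == 0)
    return(structure(list(trials = empty,
                          truth = list(person_params = NULL,
                                       ages = numeric(0),
                                       group_means = gm,
                                       group_sds = cfg$group_sds),
                          planted = list()), class = "csddm_cohort"))

  # schedule: full 16-version rotation when all versions are in play,
  # otherwise a round-robin over the requested subset
  if (length(cfg$conditions) == 16L && all(sort(cfg$conditions) == 1:16)) {
    sched <- make_schedule(n, cfg$seed + 1L)
  } else {
    k <- length(cfg$conditions)
    sched <- expand.grid(slotpos = seq_len(k), participant = seq_len(n))
    sched$version <- cfg$conditions[sched$slotpos]
    sched$day <- ((sched$slotpos - 1L) %/% 2L) + 1L
    sched$slot <- ((sched$slotpos - 1L) %% 2L) + 1L
    sched <- sched[, c("participant", "day", "slot", "version")]
  }

  set.seed(cfg$seed)
  ages <- rtruncnorm1(n, cfg$age_mean, cfg$age_sd,
                      cfg$age_range[1], cfg$age_range[2])
  zage <- if (n > 1 && sd(ages) > 0) as.numeric(scale(ages)) else rep(0, n)
  lam <- cfg$age_drift_cor
  u <- rnorm(n)
  if (n >= 3 && sd(zage) > 0 && abs(lam) < 1) {
    # residualise so the in-sample age-drift correlation is the target exactly
    e <- stats::residuals(stats::lm(u ~ zage))
    if (sd(e) > 0) e <- e / sd(e)
    u_drift <- lam * zage + sqrt(1 - lam^2) * e
  } else {
    u_drift <- lam * zage + sqrt(max(0, 1 - lam^2)) * u
  }

  # person-condition parameter table
  sds <- cfg$group_sds
  pp <- merge(expand.grid(participant = seq_len(n), version = gm$version),
              gm, by = "version")
  pp <- pp[order(pp$participant, pp$version), ]
  rownames(pp) <- NULL
  m <- nrow(pp)
  pp$drift <- pp$drift + sds[["drift"]] * u_drift[pp$participant]
  pp$bias_logit <- pp$bias_logit + sds[["bias_logit"]] * rnorm(m)
  pp$boundary_log <- pp$boundary_log + sds[["boundary_log"]] * rnorm(m)
  pp$ndt <- pmax(0.05, pp$ndt + sds[["ndt"]] * rnorm(m))
  pp$age <- ages[pp$participant]

  # session missingness at version granularity
  keep_session <- runif(nrow(sched)) >= cfg$session_missing_prob
  dropped <- sched[!keep_session, , drop = FALSE]
  live <- sched[keep_session, , drop = FALSE]

  rows <- vector("list", nrow(live))
  for (i in seq_len(nrow(live))) {
    s <- live[i, ]
    cond <- tab[s$version, ]
    par <- pp[pp$participant == s$participant & pp$version == s$version, ]
    truths <- trial_truths(cond, cfg$seed + 7919L * s$participant + s$version)
    truths <- truths[seq_len(min(cfg$trials_per_version, length(truths)))]
    rt <- numeric(length(truths)); resp <- character(length(truths))
    for (tr in c("different", "same")) {
      idx <- which(truths == tr)
      if (!length(idx)) next
      d <- ddm_params(ifelse(tr == "different", par$drift, -par$drift),
                      exp(par$boundary_log), stats::plogis(par$bias_logit),
                      par$ndt)
      sim <- sample_trials(d, length(idx))
      rt[idx] <- sim$rt * 1000
      resp[idx] <- ifelse(sim$choice == "upper", "different", "same")
    }
    over <- rt > cond$deadline_ms
    if (cfg$record_deadline_trials) {
      rt[over] <- cond$deadline_ms
    } else {
      resp[over] <- "none"; rt[over] <- NA_real_
    }
    rows[[i]] <- data.frame(
      participant_id = s$participant, age = ages[s$participant],
      day = s$day, version_index = cond$version,
      study_time_ms = cond$study_ms, change_prob = cond$change_prob,
      deadline_ms = cond$deadline_ms, probe_type = cond$probe_type,
      trial_index = seq_along(truths), truth = truths,
      response = resp, rt_ms = rt, stringsAsFactors = FALSE)
  }
  trials <- if (length(rows)) do.call(rbind, rows) else empty

  if (cfg$trial_missing_prob > 0 && nrow(trials)) {
    trials <- trials[runif(nrow(trials)) >= cfg$trial_missing_prob, ]
    rownames(trials) <- NULL
  }

  contam <- integer(0)
  responded <- which(trials$response != "none")
  if (cfg$contaminant_rate > 0 && length(responded)) {
    contam <- responded[runif(length(responded)) < cfg$contaminant_rate]
    if (length(contam)) {
      fast <- runif(length(contam)) < 0.5
      lo <- ifelse(fast, cfg$contaminant_fast_ms[1], cfg$contaminant_slow_ms[1])
      hi <- ifelse(fast, cfg$contaminant_fast_ms[2], cfg$contaminant_slow_ms[2])
      trials$rt_ms[contam] <- runif(length(contam), lo, hi)
    }
  }

  structure(list(
    trials = trials,
    truth = list(person_params = pp, ages = ages,
                 group_means = gm, group_sds = cfg$group_sds),
    planted = list(dropped_sessions = dropped, contaminant_rows = contam)),
    class = "csddm_cohort")
}

#' @export
print.csddm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d recorded trials (%d versions)\n",
              length(x$truth$ages), nrow(x$trials),
              length(unique(x$trials$version_index))))
  invisible(x)
}

#' Read and write long-format trial tables
#'
#' The on-disk schema is one row per recorded trial with columns
#' `participant_id, age, day, version_index, study_time_ms, change_prob,
#' deadline_ms, probe_type, trial_index, truth, response, rt_ms`
#' (`rt_ms` empty when `response` is `"none"`).
#'
#' @param trials A trial data.frame.
#' @param path File path.
#' @return `read_trials_csv` returns the trial data.frame.
#' @export
write_trials_csv <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  x$rt_ms <- suppressWarnings(as.numeric(x$rt_ms))
  x
}
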