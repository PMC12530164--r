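#' Apply the trial-retention rules
#'
#' Reproduces the study's trial accounting.  Scheduled trials that never
#' reached the data store are "unrecorded"; recorded trials whose response
#' window elapsed (`response == "none"`) are excluded as deadline trials;
#' responded trials with RTs faster than `rt_min` or slower than `rt_max`
#' milliseconds are excluded as out-of-bounds ("faster than"/"slower than"
#' read as strict inequalities, so RTs exactly at 200 or 7000 ms are
#' retained).  Deadline exclusion is applied first so a trial is never
#' double-counted.
#'
#' @param records Trial data.frame (schema of [write_trials_csv()]).
#' @param expected_per_participant Scheduled trials per participant (960 in
#'   the full design).
#' @param rt_min,rt_max Retention bounds in milliseconds.
#' @return A list with `retained` (the surviving rows) and `report`, an
#'   `exclusion_report` with counts and percentages of scheduled trials.
#' @export
filter_trials <- function(records, expected_per_participant = 960L,
                          rt_min = 200, rt_max = 7000) {
  responded <- records$response != "none"
  if (any(responded & (is.na(records$rt_ms) | records$rt_ms < 0)))
    stop("malformed input: responded trials must carry a nonnegative rt_ms",
         call. = FALSE)
  n_part <- length(unique(records$participant_id))
  scheduled <- n_part * expected_per_participant
  recorded <- nrow(records)
  deadline <- sum(!responded)
  oob <- responded & (records$rt_ms < rt_min | records$rt_ms > rt_max)
  retained <- records[responded & !oob, , drop = FALSE]
  rownames(retained) <- NULL
  report <- exclusion_report(scheduled = scheduled, recorded = recorded,
                             deadline_excluded = deadline,
                             rt_bound_excluded = sum(oob))
  list(retained = retained, report = report)
}

exclusion_report <- function(scheduled, recorded, deadline_excluded,
                             rt_bound_excluded) {
  unrecorded <- scheduled - recorded
  retained <- recorded - deadline_excluded - rt_bound_excluded
  counts <- c(scheduled = as.integer(scheduled), recorded = as.integer(recorded),
              unrecorded = as.integer(unrecorded),
              deadline_excluded = as.integer(deadline_excluded),
              rt_bound_excluded = as.integer(rt_bound_excluded),
              retained = as.integer(retained))
  if (any(counts < 0)) stop("exclusion counts must be nonnegative")
  structure(list(counts = counts,
                 rates = round(100 * counts / scheduled, 2)),
            class = "exclusion_report")
}

#' @export
print.exclusion_report <- function(x, ...) {
  cat("Trial accounting (% of scheduled):\n")
  for (k in names(x$counts))
    cat(sprintf("  %-18s %8d  (%6.2f%%)\n", k, x$counts[[k]], x$rates[[k]]))
  invisible(x)
}

#' Accuracy and mean RT by probe type
#'
#' A trial is correct iff the response equals the trial truth.  Accuracy is
#' reported as a percentage to 2 decimals; mean RT is over all retained
#' trials, correct and incorrect.
#'
#' @param retained Retained trial data.frame (see [filter_trials()]).
#' @return A data.frame with rows `Overall` plus one per probe type:
#'   `correct`, `total`, `accuracy_pct`, `mean_rt_ms`.
#' @export
accuracy_summary <- function(retained) {
  if (!nrow(retained))
    return(data.frame(probe_type = character(0), correct = integer(0),
                      total = integer(0), accuracy_pct = numeric(0),
                      mean_rt_ms = numeric(0)))
  one <- function(d, label) data.frame(
    probe_type = label, correct = sum(d$response == d$truth),
    total = nrow(d),
    accuracy_pct = round(100 * sum(d$response == d$truth) / nrow(d), 2),
    mean_rt_ms = round(mean(d$rt_ms), 2), stringsAsFactors = FALSE)
  out <- rbind(one(retained, "Overall"),
               do.call(rbind, lapply(split(retained, retained$probe_type),
                                     function(d) one(d, d$probe_type[1]))))
  rownames(out) <- NULL
  out
}

#' Participant engagement summary
#'
#' Per participant, the number of versions completed (a version counts as
#' completed when at least one of its trials was recorded) and trials
#' recorded, then the distribution of participants over completion levels.
#'
#' @inheritParams filter_trials
#' @return A list with `per_participant` and `distribution` data.frames;
#'   `completion_pct` is trials recorded as % of expected, to 1 decimal.
#' @export
engagement_summary <- function(records, expected_per_participant = 960L) {
  per <- do.call(rbind, lapply(split(records, records$participant_id),
    function(d) data.frame(
      participant_id = d$participant_id[1],
      trials_completed = nrow(d),
      versions_completed = length(unique(d$version_index)),
      completion_pct = round(100 * nrow(d) / expected_per_participant, 1),
      stringsAsFactors = FALSE)))
  rownames(per) <- NULL
  key <- interaction(per$completion_pct, per$trials_completed,
                     per$versions_completed, drop = TRUE)
  dist <- do.call(rbind, lapply(split(per, key), function(d) data.frame(
    completion_pct = d$completion_pct[1],
    trials_completed = d$trials_completed[1],
    versions_completed = d$versions_completed[1],
    participants = nrow(d),
    participants_pct = round(100 * nrow(d) / nrow(per)),
    stringsAsFactors = FALSE)))
  dist <- dist[order(-dist$completion_pct, -dist$versions_completed), ]
  rownames(dist) <- NULL
  list(per_participant = per, distribution = dist)
}
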