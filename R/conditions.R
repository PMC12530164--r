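#' The 16 task versions of the factorial design
#'
#' The Color Shapes task crosses four binary factors within person:
#' study time (500 vs 2000 ms), probability of change (50% vs 80%
#' "different" trials), choice urgency (10,000 vs 3000 ms response window)
#' and probe type (whole display of 3 shapes vs a single probe).  Each of
#' the 16 combinations is one task "version"; every participant plays each
#' version once (60 trials) over 8 days, 2 versions per day.
#'
#' @return A data.frame with one row per version: `version` (1..16), the
#'   four factor columns, and the derived `study_ms`, `deadline_ms` and
#'   `p_different` columns.
#' @examples
#' condition_table()
#' @export
condition_table <- function() {
  tab <- expand.grid(
    study_time  = c("short_500ms", "long_2000ms"),
    change_prob = c("low_50", "high_80"),
    urgency     = c("minimal_10000ms", "high_3000ms"),
    probe_type  = c("whole_display", "single_probe"),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab <- cbind(version = seq_len(nrow(tab)), tab)
  tab$study_ms    <- ifelse(tab$study_time == "short_500ms", 500L, 2000L)
  tab$deadline_ms <- ifelse(tab$urgency == "high_3000ms", 3000L, 10000L)
  tab$p_different <- ifelse(tab$change_prob == "high_80", 0.8, 0.5)
  tab
}

condition_factors <- c("study_time", "change_prob", "urgency", "probe_type")

# focal factor and manipulated/baseline levels for each contrasted parameter
contrast_map <- function() {
  data.frame(
    parameter   = c("drift", "bias_logit", "boundary_log"),
    factor      = c("study_time", "change_prob", "urgency"),
    manipulated = c("long_2000ms", "high_80", "high_3000ms"),
    baseline    = c("short_500ms", "low_50", "minimal_10000ms"),
    stringsAsFactors = FALSE)
}

#' Randomised version schedules
#'
#' Assigns the 16 task versions to 8 days x 2 versions per day for each
#' participant.  Orderings are drawn from a pool of 3 fixed random
#' permutations (generated from `seed`), mirroring the study's use of 3
#' rotation schedules; each participant gets one of the 3, uniformly at
#' random.
#'
#' @param n_participants Number of participants (>= 0).
#' @param seed Integer seed.
#' @return A data.frame with columns `participant`, `day` (1..8), `slot`
#'   (1..2) and `version` (1..16); every participant sees each version
#'   exactly once.
#' @export
make_schedule <- function(n_participants, seed) {
  stopifnot(n_participants >= 0)
  set.seed(seed)
  pool <- replicate(3, sample.int(16L), simplify = FALSE)
  if (n_participants == 0)
    return(data.frame(participant = integer(0), day = integer(0),
                      slot = integer(0), version = integer(0)))
  pick <- sample.int(3L, n_participants, replace = TRUE)
  do.call(rbind, lapply(seq_len(n_participants), function(i) {
    data.frame(participant = i, day = rep(1:8, each = 2L),
               slot = rep(1:2, 8L), version = pool[[pick[i]]])
  }))
}

#' Trial truth sequence for one version
#'
#' Generates the 60 trial truths of a session with the exact composition
#' implied by the change-probability factor: 48 "different" / 12 "same" in
#' the high-change versions, 30/30 in the low-change versions, in an order
#' permuted by `seed`.
#'
#' @param version A row of [condition_table()] or a version index 1..16.
#' @param seed Integer seed.
#' @return Character vector of length 60 with values `"different"`/`"same"`.
#' @export
trial_truths <- function(version, seed) {
  if (is.numeric(version)) version <- condition_table()[version, ]
  n_diff <- if (version$change_prob == "high_80") 48L else 30L
  truths <- c(rep("different", n_diff), rep("same", 60L - n_diff))
  set.seed(seed)
  sample(truths)
}
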