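#' Posterior predictive simulation
#'
#' Simulates full datasets under the observed design: for each of `n_sim`
#' posterior draws (resampled with replacement when `n_sim` exceeds the
#' number of stored draws), every person-condition cell is re-simulated
#' with its drawn parameters, with the same number of trials and the same
#' truth composition as observed.  Trials whose simulated RT exceeds the
#' condition's response deadline are kept (so per-cell trial counts are
#' preserved exactly) but flagged `over_deadline`, and downstream checks
#' drop them exactly as the preprocessing pipeline drops observed
#' deadline trials.
#'
#' @param fit A `csddm_fit`.
#' @param n_sim Number of predictive datasets (the study's check used
#'   6000; scaled-down checks typically use 200).
#' @param seed Optional integer seed.
#' @param n_grid Grid size of the inverse-CDF sampler.
#' @return An object of class `csddm_ppc`: `sims` (list of data.frames
#'   with `cell`, `version`, `truth`, `choice`, `rt` in seconds,
#'   `over_deadline`) and `draw_index`.
#' @export
posterior_predictive <- function(fit, n_sim = 6000, seed = NULL,
                                 n_grid = 1024) {
  stopifnot(inherits(fit, "csddm_fit"), n_sim >= 1)
  if (!is.null(seed)) set.seed(seed)
  ndraw <- dim(fit$draws$theta)[1]
  draw_index <- if (n_sim <= ndraw) sample.int(ndraw, n_sim)
                else sample.int(ndraw, n_sim, replace = TRUE)
  dat <- fit$data
  # observed design: trials per cell and truth
  key <- paste(dat$cell, ifelse(dat$sign > 0, "different", "same"))
  counts <- table(key)
  cell_of <- as.integer(sub(" .*", "", names(counts)))
  truth_of <- sub(".* ", "", names(counts))
  deadline_s <- dat$cond_info$deadline_ms[dat$cellcond] / 1000

  sims <- vector("list", n_sim)
  for (s in seq_len(n_sim)) {
    th <- fit$draws$theta[draw_index[s], , ]
    if (dat$ncell == 1) th <- matrix(th, ncol = 1)
    parts <- vector("list", length(counts))
    for (j in seq_along(counts)) {
      cl <- cell_of[j]
      drift <- th[1, cl] * if (truth_of[j] == "different") 1 else -1
      p <- ddm_params(drift, exp(th[3, cl]), stats::plogis(th[2, cl]),
                      th[4, cl])
      g <- wfpt_cdf_grid(p, n_grid = n_grid)
      n <- as.integer(counts[j])
      pu <- prob_upper(p)
      up <- runif(n) < pu
      tot_u <- g$cdf_upper[length(g$t)]; tot_l <- g$cdf_lower[length(g$t)]
      rt <- numeric(n)
      inv <- function(cdf, tot, m) {
        u <- runif(m) * tot
        keep <- c(TRUE, diff(cdf) > 0)
        approx(cdf[keep], g$t[keep], xout = u, rule = 2)$y
      }
      if (any(up)) rt[up] <- inv(g$cdf_upper, tot_u, sum(up))
      if (any(!up)) rt[!up] <- inv(g$cdf_lower, tot_l, sum(!up))
      rt <- rt + p$ndt
      parts[[j]] <- data.frame(
        cell = cl, version = dat$conds[dat$cellcond[cl]],
        truth = truth_of[j],
        choice = ifelse(up, "different", "same"), rt = rt,
        over_deadline = rt > deadline_s[cl], stringsAsFactors = FALSE)
    }
    sims[[s]] <- do.call(rbind, parts)
  }
  structure(list(sims = sims, draw_index = draw_index),
            class = "csddm_ppc")
}

#' @export
print.csddm_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive simulation: %d datasets of %d trials\n",
              length(x$sims), nrow(x$sims[[1]])))
  invisible(x)
}

#' Posterior predictive RT-quantile check
#'
#' Compares observed RT quantiles, split by condition and correctness
#' (response equals truth), against the across-simulation median and
#' central 95% predictive band at the same levels.  Condition x
#' correctness cells with fewer than 5 observed trials are flagged and
#' skipped (their quantiles are unstable).  Quantiles use linear
#' interpolation of order statistics (R type 7) throughout.
#'
#' @param observed Retained trial data.frame (with `rt_ms`).
#' @param ppc A `csddm_ppc` from [posterior_predictive()].
#' @param levels Quantile levels, default the RT-quantile convention
#'   `c(0.1, 0.3, 0.5, 0.7, 0.9)`.
#' @return An object of class `csddm_ppc_check`: `table` (one row per
#'   condition x correctness x level with observed value, predictive
#'   median and band), `coverage` (fraction of observed quantiles inside
#'   their bands), and `skipped` (flagged sparse cells).
#' @export
rt_quantile_check <- function(observed, ppc,
                              levels = c(0.1, 0.3, 0.5, 0.7, 0.9)) {
  stopifnot(inherits(ppc, "csddm_ppc"))
  obs <- data.frame(version = observed$version_index,
                    rt = observed$rt_ms / 1000,
                    correctness = ifelse(observed$response == observed$truth,
                                         "correct", "error"),
                    stringsAsFactors = FALSE)
  cells <- unique(obs[, c("version", "correctness")])
  cells <- cells[order(cells$version, cells$correctness), ]
  rows <- list(); skipped <- list()
  for (i in seq_len(nrow(cells))) {
    v <- cells$version[i]; corr <- cells$correctness[i]
    o <- obs$rt[obs$version == v & obs$correctness == corr]
    if (length(o) < 5) {
      skipped[[length(skipped) + 1]] <- data.frame(
        version = v, correctness = corr, n_obs = length(o))
      next
    }
    oq <- quantile(o, levels, type = 7, names = FALSE)
    simq <- vapply(ppc$sims, function(s) {
      keep <- s$version == v & !s$over_deadline &
        (ifelse(s$choice == s$truth, "correct", "error") == corr)
      if (sum(keep) < 2) return(rep(NA_real_, length(levels)))
      quantile(s$rt[keep], levels, type = 7, names = FALSE)
    }, numeric(length(levels)))
    rows[[length(rows) + 1]] <- data.frame(
      version = v, correctness = corr, level = levels, n_obs = length(o),
      observed = oq,
      pred_median = apply(simq, 1, median, na.rm = TRUE),
      pred_low = apply(simq, 1, quantile, 0.025, na.rm = TRUE, names = FALSE),
      pred_high = apply(simq, 1, quantile, 0.975, na.rm = TRUE, names = FALSE),
      stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  cov <- mean(tab$observed >= tab$pred_low & tab$observed <= tab$pred_high,
              na.rm = TRUE)
  structure(list(table = tab, coverage = cov,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else NULL,
                 levels = levels),
            class = "csddm_ppc_check")
}

#' @export
print.csddm_ppc_check <- function(x, ...) {
  cat(sprintf(
    "RT-quantile posterior predictive check: coverage %.3f (%d quantiles, %d skipped cells)\n",
    x$coverage, nrow(x$table),
    if (is.null(x$skipped)) 0L else nrow(x$skipped)))
  invisible(x)
}
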