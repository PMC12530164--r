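#' @export
print.csddm_fit <- function(x, ...) {
  cat("Multilevel drift diffusion model fit\n")
  cat(sprintf("  %d trials, %d participants, %d conditions, %d cells\n",
              x$data$n_trials, length(x$data$persons), length(x$data$conds),
              x$data$ncell))
  cat(sprintf("  %d chains x %d draws (%d warmup), %.1f s\n",
              x$spec$chains, x$spec$draws, x$spec$warmup, x$runtime_s))
  if (x$spec$fix_bias) cat("  restricted model: start point fixed at 0.5\n")
  bad <- sum(x$diagnostics$table$rhat > x$spec$rhat_threshold, na.rm = TRUE)
  cat(sprintf("  convergence: max split R-hat %.3f (%s)\n",
              max(x$diagnostics$table$rhat, na.rm = TRUE),
              if (x$diagnostics$converged) "ok"
              else paste(bad, "parameters flagged")))
  invisible(x)
}

#' Summarise a multilevel DDM fit
#'
#' @param object A `csddm_fit`.
#' @param ... Unused.
#' @return A list of class `summary.csddm_fit`: `conditions` (marginal
#'   condition summaries), `contrasts` (manipulation contrasts) and
#'   `diagnostics` (split R-hat / ESS table).
#' @export
summary.csddm_fit <- function(object, ...) {
  structure(list(conditions = condition_summaries(object),
                 contrasts = contrasts_csddm(object),
                 diagnostics = object$diagnostics$table),
            class = "summary.csddm_fit")
}

#' @export
print.summary.csddm_fit <- function(x, digits = 3, ...) {
  fmt <- function(d) {
    d$mean <- round(d$mean, digits); d$sd <- round(d$sd, digits)
    d$ci_low <- round(d$ci_low, digits); d$ci_high <- round(d$ci_high, digits)
    d
  }
  cat("Marginal condition summaries (group means, sampling scales):\n")
  print(fmt(x$conditions), row.names = FALSE)
  cat("\nManipulation contrasts (manipulated - baseline):\n")
  print(fmt(x$contrasts), row.names = FALSE)
  cat(sprintf("\nDiagnostics: max split R-hat %.3f, min ESS %.0f\n",
              max(x$diagnostics$rhat, na.rm = TRUE),
              min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' Posterior-mean group-level coefficients
#'
#' @param object A `csddm_fit`.
#' @param ... Unused.
#' @return Matrix of posterior-mean group means, parameters x conditions.
#' @export
coef.csddm_fit <- function(object, ...) {
  apply(object$draws$mu, c(2, 3), mean)
}

#' Simulate datasets from the fitted posterior
#'
#' A thin wrapper around [posterior_predictive()] following the base-R
#' `simulate` convention.
#'
#' @param object A `csddm_fit`.
#' @param nsim Number of posterior predictive datasets.
#' @param seed Optional integer seed.
#' @param ... Passed to [posterior_predictive()].
#' @return See [posterior_predictive()].
#' @export
simulate.csddm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  posterior_predictive(object, n_sim = nsim, seed = seed, ...)
}

#' Plot posterior predictive RT quantiles
#'
#' Observed RT quantiles (filled circles correct, open circles error)
#' against the posterior predictive median and central 95% band, one panel
#' per condition.
#'
#' @param x A `csddm_ppc_check` from [rt_quantile_check()].
#' @param ... Unused.
#' @export
plot.csddm_ppc_check <- function(x, ...) {
  tab <- x$table
  conds <- unique(tab$version)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(conds)),
                       mar = c(3.5, 3.5, 2, 0.5), mgp = c(2.2, 0.7, 0))
  on.exit(graphics::par(old))
  for (v in conds) {
    d <- tab[tab$version == v, ]
    rng <- range(c(d$observed, d$pred_low, d$pred_high), na.rm = TRUE)
    graphics::plot(NA, xlim = range(d$level), ylim = rng,
                   xlab = "quantile level", ylab = "RT (s)",
                   main = paste("version", v))
    for (corr in unique(d$correctness)) {
      dd <- d[d$correctness == corr, ]
      graphics::polygon(c(dd$level, rev(dd$level)),
                        c(dd$pred_low, rev(dd$pred_high)),
                        col = grDevices::adjustcolor("grey50", 0.3), border = NA)
      graphics::lines(dd$level, dd$pred_median, col = "grey30")
      graphics::points(dd$level, dd$observed,
                       pch = if (corr == "correct") 19 else 1)
    }
  }
  invisible(x)
}
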