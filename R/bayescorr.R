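# Gauss hypergeometric 2F1(a, b; c; z) by direct series, adequate for the
# correlation likelihood where 0 <= z < 1 and c grows with n.
hyp2f1 <- function(a, b, cc, z, tol = 1e-12, max_terms = 100000) {
  term <- 1; s <- 1
  for (j in seq_len(max_terms)) {
    term <- term * (a + j - 1) * (b + j - 1) / (cc + j - 1) * z / j
    s <- s + term
    if (abs(term) < tol * abs(s)) return(s)
  }
  warning("hypergeometric series did not converge")
  s
}

# log likelihood kernel of the sample correlation r given the population
# correlation rho at sample size n (rho-free factors dropped; they cancel
# in the Bayes factor and the posterior normalisation)
log_r_kernel <- function(rho, r, n) {
  ((n - 1) / 2) * log1p(-rho^2) - ((2 * n - 3) / 2) * log1p(-rho * r) +
    log(hyp2f1(0.5, 0.5, (2 * n - 1) / 2, (1 + rho * r) / 2))
}

# symmetric stretched-beta prior density on (-1, 1) with width kappa
stretched_beta <- function(rho, kappa = 1) {
  stats::dbeta((rho + 1) / 2, 1 / kappa, 1 / kappa) / 2
}

#' Bayesian Pearson correlation with Bayes factor
#'
#' Sample Pearson correlation together with the Bayes factor BF10 of a
#' correlation model (symmetric stretched-beta prior on the population
#' correlation, width `prior_width`, two-sided) against the null of zero
#' correlation, computed by adaptive quadrature of the exact sampling
#' density of r over the prior; the central 95% credible interval comes
#' from the normalised posterior on a fine grid.  `prior_width = 1` (a
#' uniform prior on the correlation) matches the default of standard
#' Bayesian-statistics GUIs.
#'
#' @param x,y Numeric vectors of equal length `n >= 4` with nonzero
#'   variance.
#' @param prior_width Width of the stretched-beta prior.
#' @return An object of class `correlation_result`: `r`, `bf10`, `ci_low`,
#'   `ci_high`, `evidence` (label per [evidence_label()]), `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(40); y <- 0.5 * x + rnorm(40)
#' pearson_bf(x, y)
#' @export
pearson_bf <- function(x, y, prior_width = 1) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) stop("insufficient data: need n >= 4 complete pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite", call. = FALSE)
  if (var(x) == 0 || var(y) == 0)
    stop("degenerate input: zero variance", call. = FALSE)
  r <- cor(x, y)
  # |r| = 1 carries unbounded evidence; clamp for the numerics only
  r_num <- sign(r) * min(abs(r), 1 - 1e-6)
  lg0 <- log_r_kernel(0, r_num, n)
  # split the quadrature at the likelihood peak (near rho = r) so the
  # adaptive rule resolves sharply peaked integrands at large |r|
  intgr <- function(rho) exp(vapply(rho, log_r_kernel, 0, r = r_num, n = n) -
                               lg0) * stretched_beta(rho, prior_width)
  bf10 <- integrate(intgr, -1, r_num, rel.tol = 1e-6)$value +
    integrate(intgr, r_num, 1, rel.tol = 1e-6)$value
  # posterior of the population correlation on a grid
  grid <- seq(-1 + 1e-6, 1 - 1e-6, length.out = 4001)
  lp <- vapply(grid, log_r_kernel, 0, r = r_num, n = n) +
    log(stretched_beta(grid, prior_width))
  w <- exp(lp - max(lp))
  cdf <- cumtrapz(grid, w); cdf <- cdf / cdf[length(cdf)]
  keep <- c(TRUE, diff(cdf) > 0)
  ci <- approx(cdf[keep], grid[keep], xout = c(0.025, 0.975), rule = 2)$y
  structure(list(r = r, bf10 = bf10, ci_low = ci[1], ci_high = ci[2],
                 evidence = evidence_label(bf10), n = n,
                 prior_width = prior_width),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d), BF10 = %.4g [%s], 95%% CI (%.3f, %.3f)\n",
              x$r, x$n, x$bf10, x$evidence, x$ci_low, x$ci_high))
  invisible(x)
}

#' Evidence category of a Bayes factor
#'
#' Maps BF10 to the conventional evidence bands: 1-3 anecdotal, 3-10
#' moderate, 10-30 strong, 30-100 very strong, above 100 extreme.  Bayes
#' factors below 1 are labelled by the mirrored band of the reciprocal
#' with the suffix `"(null)"` (e.g. BF10 = 0.16 means 1/0.16 = 6.25,
#' "moderate (null)").
#'
#' @param bf10 Positive Bayes factor.
#' @return Character label.
#' @export
evidence_label <- function(bf10) {
  if (!is.finite(bf10) || bf10 <= 0)
    stop("bf10 must be a positive real", call. = FALSE)
  band <- function(b) {
    if (b < 3) "anecdotal" else if (b < 10) "moderate"
    else if (b < 30) "strong" else if (b < 100) "very strong" else "extreme"
  }
  if (bf10 >= 1) band(bf10) else paste(band(1 / bf10), "(null)")
}

#' Correlate person-level DDM parameters with covariates
#'
#' Runs [pearson_bf()] for each parameter x covariate x grouping (overall
#' and stratified by probe type), on person-level posterior means from
#' [person_parameter_table()].  Degenerate cells (zero variance, too few
#' pairs) are reported with the error message and the scan continues.
#'
#' @param fit A `csddm_fit`.
#' @param covariates Data.frame of person-level covariates, one row per
#'   participant in the fit (e.g. `data.frame(age = ...)`).
#' @param parameters Parameters to scan.
#' @param groupings Condition groupings to scan.
#' @param prior_width Passed to [pearson_bf()].
#' @return A data.frame with one row per combination: `parameter`,
#'   `covariate`, `grouping`, `r`, `bf10`, `ci_low`, `ci_high`,
#'   `evidence`, `error`.
#' @export
parameter_covariate_scan <- function(fit, covariates,
                                     parameters = c("drift", "bias_logit",
                                                    "boundary_log"),
                                     groupings = c("overall", "whole_display",
                                                   "single_probe"),
                                     prior_width = 1) {
  stopifnot(nrow(covariates) == length(fit$data$persons))
  rows <- list()
  for (g in groupings) {
    tab <- tryCatch(person_parameter_table(fit, g), error = function(e) NULL)
    if (is.null(tab)) next
    for (p in parameters) {
      if (fit$spec$fix_bias && p == "bias_logit") next
      for (cv in names(covariates)) {
        res <- tryCatch(pearson_bf(tab[[p]], covariates[[cv]], prior_width),
                        error = function(e) e)
        rows[[length(rows) + 1]] <- if (inherits(res, "error")) {
          data.frame(parameter = p, covariate = cv, grouping = g,
                     r = NA_real_, bf10 = NA_real_, ci_low = NA_real_,
                     ci_high = NA_real_, evidence = NA_character_,
                     error = conditionMessage(res), stringsAsFactors = FALSE)
        } else {
          data.frame(parameter = p, covariate = cv, grouping = g,
                     r = res$r, bf10 = res$bf10, ci_low = res$ci_low,
                     ci_high = res$ci_high, evidence = res$evidence,
                     error = NA_character_, stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
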