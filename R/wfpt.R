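#' Drift diffusion model parameters for one person-condition cell
#'
#' Bundles the four parameters of the two-boundary Wiener diffusion model on
#' their natural scales, with the scaling convention that the within-trial
#' diffusion coefficient is 1 and time is measured in seconds.  The upper
#' boundary is the "Different" response, the lower boundary "Same".
#'
#' @param drift Drift rate (evidence units per second); positive values drive
#'   the process toward the upper ("Different") boundary.
#' @param boundary Boundary separation, must be positive.
#' @param bias Relative start point in (0, 1); the process starts at
#'   `boundary * bias`.  Values above 0.5 favour the upper boundary.
#' @param ndt Nondecision time in seconds (encoding + motor execution),
#'   must be nonnegative.
#' @return An object of class `ddm_params`.
#' @examples
#' p <- ddm_params(drift = 1, boundary = 1, bias = 0.5, ndt = 0.3)
#' prob_upper(p)
#' @export
ddm_params <- function(drift, boundary, bias, ndt = 0) {
  p <- list(drift = as.numeric(drift), boundary = as.numeric(boundary),
            bias = as.numeric(bias), ndt = as.numeric(ndt))
  validate_ddm_params(p)
  class(p) <- "ddm_params"
  p
}

validate_ddm_params <- function(p) {
  if (!is.finite(p$drift)) stop("drift must be finite", call. = FALSE)
  if (!is.finite(p$boundary) || p$boundary <= 0)
    stop("boundary must be a positive real", call. = FALSE)
  if (!is.finite(p$bias) || p$bias <= 0 || p$bias >= 1)
    stop("bias must lie strictly in (0, 1)", call. = FALSE)
  if (!is.finite(p$ndt) || p$ndt < 0)
    stop("ndt must be nonnegative", call. = FALSE)
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf(
    "DDM parameters: drift = %.3f, boundary = %.3f, bias = %.3f, ndt = %.3f s\n",
    x$drift, x$boundary, x$bias, x$ndt))
  invisible(x)
}

#' Log density of the Wiener first-passage time
#'
#' Joint log density of (response time = `t`, absorbed boundary = `choice`)
#' under the two-boundary Wiener diffusion model.  The density at the lower
#' boundary is evaluated through small-time and large-time series expansions,
#' choosing per evaluation the representation that needs fewer terms at
#' truncation error `eps`; the upper-boundary density follows by the
#' reflection mapping (drift to -drift, bias to 1 - bias).
#'
#' Response times at or before the nondecision time carry no decision mass and
#' return `-Inf` rather than raising, so the likelihood is defined for any
#' observed RT and data cleaning stays in the preprocessing layer.
#'
#' @param t Vector of response times in seconds.
#' @param choice `"upper"`/`"lower"` (or a logical vector, `TRUE` = upper),
#'   recycled against `t`.
#' @param params A [ddm_params] object.
#' @param eps Series truncation error tolerance.
#' @return Vector of log densities, `-Inf` where `t <= ndt`.
#' @export
wfpt_logdensity <- function(t, choice, params, eps = 1e-10) {
  validate_ddm_params(params)
  up <- choice_to_upper(choice)
  if (length(up) < length(t)) up <- rep_len(up, length(t))
  stopifnot(length(up) == length(t))
  wfpt_logdens_cpp(as.numeric(t), as.integer(up), params$drift,
                   params$boundary, params$bias, params$ndt, eps)
}

choice_to_upper <- function(choice) {
  if (is.logical(choice)) return(as.integer(choice))
  if (is.numeric(choice)) return(as.integer(choice != 0))
  ch <- match.arg(as.character(choice), c("upper", "lower"), several.ok = TRUE)
  as.integer(ch == "upper")
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form probability that the diffusion terminates at the upper
#' ("Different") boundary:
#' \deqn{P = \frac{1 - e^{-2\delta\alpha\beta}}{1 - e^{-2\delta\alpha}}}
#' for nonzero drift, and `bias` for driftless processes.
#'
#' @param params A [ddm_params] object.
#' @return A probability in (0, 1).
#' @export
prob_upper <- function(params) {
  validate_ddm_params(params)
  v <- params$drift; a <- params$boundary; w <- params$bias
  if (abs(v) < 1e-12) return(w)
  x <- -2 * v * a
  # expm1 keeps precision for small |drift * boundary|
  expm1(x * w) / expm1(x)
}

#' Decision-time distribution on a grid
#'
#' Numerically integrated CDF of the decision time (RT minus nondecision
#' time), per boundary, on a quadratically spaced grid that is dense near
#' zero.  The grid extends until the unaccounted tail mass drops below
#' `tail_tol`.  Used by the inverse-CDF sampler and by validation checks.
#'
#' @param params A [ddm_params] object.
#' @param n_grid Number of grid points.
#' @param tail_tol Upper bound on the truncated tail mass.
#' @return A list with `t` (decision times), `cdf_upper`, `cdf_lower`
#'   (unconditional, so `cdf_upper` tends to `prob_upper(params)`).
#' @keywords internal
wfpt_cdf_grid <- function(params, n_grid = 4096, tail_tol = 1e-6) {
  validate_ddm_params(params)
  p0 <- ddm_params(params$drift, params$boundary, params$bias, 0)
  tmax <- max(2, 6 * params$boundary^2 / (1 + params$drift^2))
  repeat {
    tt <- tmax * (seq_len(n_grid) / n_grid)^2
    fu <- exp(wfpt_logdensity(tt, rep(TRUE, n_grid), p0))
    fl <- exp(wfpt_logdensity(tt, rep(FALSE, n_grid), p0))
    cu <- cumtrapz(tt, fu)
    cl <- cumtrapz(tt, fl)
    if (1 - (cu[n_grid] + cl[n_grid]) < tail_tol) break
    tmax <- tmax * 2
    if (tmax > 1e5) stop("failed to bracket the first-passage distribution")
  }
  list(t = tt, cdf_upper = cu, cdf_lower = cl)
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum(diff(x) * (y[-1] + y[-n]) / 2))
}

#' Sample choices and response times from the diffusion model
#'
#' Draws from the exact joint (choice, RT) law: the boundary is drawn from
#' the closed-form absorption probability and the decision time by inversion
#' of the numerically integrated conditional CDF, then the nondecision time
#' is added.  No discretised path simulation is involved.
#'
#' @param params A [ddm_params] object.
#' @param n Number of trials.
#' @param seed Optional integer seed; when supplied the draw is reproducible.
#' @return A data.frame with columns `choice` (`"upper"`/`"lower"`) and
#'   `rt` (seconds, always greater than `ndt`).
#' @export
sample_trials <- function(params, n, seed = NULL) {
  validate_ddm_params(params)
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (n == 0)
    return(data.frame(choice = character(0), rt = numeric(0)))
  g <- wfpt_cdf_grid(params)
  pu <- prob_upper(params)
  up <- stats::runif(n) < pu
  rt <- numeric(n)
  tot_u <- g$cdf_upper[length(g$t)]
  tot_l <- g$cdf_lower[length(g$t)]
  inv <- function(cdf, tot, m) {
    u <- stats::runif(m) * tot
    keep <- c(TRUE, diff(cdf) > 0)  # approx() needs strictly increasing x
    stats::approx(cdf[keep], g$t[keep], xout = u, rule = 2)$y
  }
  if (any(up))  rt[up]  <- inv(g$cdf_upper, tot_u, sum(up))
  if (any(!up)) rt[!up] <- inv(g$cdf_lower, tot_l, sum(!up))
  data.frame(choice = ifelse(up, "upper", "lower"),
             rt = rt + params$ndt, stringsAsFactors = FALSE)
}

#' Discretised reference simulator (Euler-Maruyama)
#'
#' Simulates diffusion paths with a fixed-step Euler-Maruyama scheme.  This
#' carries discretisation bias of order `sqrt(dt)` and exists purely as an
#' independent cross-check for the exact density and sampler; it is never
#' used in production sampling.
#'
#' @inheritParams sample_trials
#' @param dt Time step in seconds.
#' @param tmax Censoring horizon for unabsorbed paths.
#' @return A data.frame with columns `choice` and `rt`.
#' @export
sample_trials_em <- function(params, n, seed = NULL, dt = 1e-4, tmax = 30) {
  validate_ddm_params(params)
  if (!is.null(seed)) set.seed(seed)
  m <- sim_ddm_em_cpp(n, params$drift, params$boundary, params$bias,
                      params$ndt, dt, tmax)
  data.frame(choice = ifelse(m[, 1] == 1, "upper", "lower"), rt = m[, 2],
             stringsAsFactors = FALSE)
}
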