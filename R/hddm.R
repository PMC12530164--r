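#' Sampler and model settings for the multilevel DDM
#'
#' All four DDM parameters vary by person and condition on their sampling
#' scales (drift natural, bias logit, boundary log, nondecision time in
#' seconds), with person-condition values drawn from condition-specific
#' normal group distributions.  Priors are weakly informative and
#' configurable; `fix_bias = TRUE` fits the restricted no-bias model
#' (start point pinned at 0.5), used for misspecification checks.
#'
#' @param chains Number of MCMC chains (>= 2 for convergence diagnostics;
#'   1 is allowed for quick experiments).
#' @param warmup,draws Iterations discarded / retained per chain.
#' @param priors List of `c(location, scale)` pairs for the group means of
#'   `mu_drift`, `mu_bias` (logit), `mu_boundary` (log), `mu_ndt`
#'   (seconds, truncated at 0), plus `sd_scale`, the half-normal scale of
#'   all group SDs.
#' @param fix_bias Fit with the start point fixed at 0.5.
#' @param rhat_threshold Split-R-hat above which a group-level parameter is
#'   flagged as nonconverged.
#' @param eps Truncation tolerance of the Wiener density series.
#' @param seed Integer seed.
#' @return An object of class `csddm_spec`.
#' @export
csddm_spec <- function(chains = 4, warmup = 1000, draws = 1000,
                       priors = list(mu_drift = c(0, 3),
                                     mu_bias = c(0, 1.5),
                                     mu_boundary = c(0, 1.5),
                                     mu_ndt = c(0.3, 0.3),
                                     sd_scale = 1),
                       fix_bias = FALSE, rhat_threshold = 1.01,
                       eps = 1e-7, seed = 1L) {
  stopifnot(chains >= 1, draws >= 1, warmup >= 0)
  for (p in c("mu_drift", "mu_bias", "mu_boundary", "mu_ndt"))
    if (priors[[p]][2] <= 0) stop("prior scales must be positive")
  if (priors$sd_scale <= 0) stop("prior scales must be positive")
  structure(as.list(environment()), class = "csddm_spec")
}

ddm_param_names <- c("drift", "bias_logit", "boundary_log", "ndt")

# Assemble the per-trial structures the sampler needs.
csddm_data <- function(records) {
  if (!nrow(records)) stop("empty data: no retained trials", call. = FALSE)
  if (any(is.na(records$rt_ms)) || any(records$rt_ms <= 0))
    stop("all retained trials must have a positive rt_ms", call. = FALSE)
  rt <- records$rt_ms / 1000                     # model works in seconds
  persons <- sort(unique(records$participant_id))
  conds <- sort(unique(records$version_index))
  pid <- match(records$participant_id, persons)
  cid <- match(records$version_index, conds)
  cellkey <- (pid - 1L) * length(conds) + cid
  cells <- sort(unique(cellkey))
  cell <- match(cellkey, cells)
  ncell <- length(cells)
  list(rt = rt,
       upper = as.integer(records$response == "different"),
       sign = ifelse(records$truth == "different", 1, -1),
       cell = cell, ncell = ncell,
       cellperson = ((cells - 1L) %/% length(conds)) + 1L,
       cellcond = ((cells - 1L) %% length(conds)) + 1L,
       minrt = as.numeric(tapply(rt, cell, min)),
       persons = persons, conds = conds,
       cond_info = condition_table()[conds, , drop = FALSE],
       n_trials = length(rt))
}

# Joint log density (likelihood + hierarchical priors + hyperpriors) at one
# parameter state; the additive structure is itself a tested contract.
csddm_joint_logdensity <- function(dat, theta, mu, sig, spec) {
  ll <- sum(wfpt_loglik_cells_cpp(dat$rt, dat$upper, dat$cell, dat$sign,
                                  theta[1, ], exp(theta[3, ]),
                                  stats::plogis(theta[2, ]), theta[4, ],
                                  dat$ncell, spec$eps))
  cc <- dat$cellcond
  pr <- sum(dnorm(theta[1, ], mu[1, cc], sig[1, cc], log = TRUE)) +
    sum(dnorm(theta[3, ], mu[3, cc], sig[3, cc], log = TRUE)) +
    sum(dnorm(theta[4, ], mu[4, cc], sig[4, cc], log = TRUE))
  if (!spec$fix_bias)
    pr <- pr + sum(dnorm(theta[2, ], mu[2, cc], sig[2, cc], log = TRUE))
  hp <- sum(dnorm(mu[1, ], spec$priors$mu_drift[1], spec$priors$mu_drift[2], log = TRUE)) +
    sum(dnorm(mu[3, ], spec$priors$mu_boundary[1], spec$priors$mu_boundary[2], log = TRUE)) +
    sum(dnorm(mu[4, ], spec$priors$mu_ndt[1], spec$priors$mu_ndt[2], log = TRUE)) +
    sum(dnorm(sig, 0, spec$priors$sd_scale, log = TRUE))
  if (!spec$fix_bias)
    hp <- hp + sum(dnorm(mu[2, ], spec$priors$mu_bias[1], spec$priors$mu_bias[2], log = TRUE))
  ll + pr + hp
}

qtruncnorm0 <- function(u, mean, sd) {
  # quantile of N(mean, sd) truncated to [0, Inf)
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + u * (1 - p0), mean, sd)
}

#' Fit the multilevel drift diffusion model
#'
#' Fits the hierarchical Bayesian DDM to retained trial data: every person
#' x condition cell gets its own drift, start point (logit scale), boundary
#' separation (log scale) and nondecision time, tied together by
#' condition-level normal group distributions, all estimated jointly in a
#' single MCMC run.  Drift is stimulus-coded: the cell-level drift
#' magnitude enters positively on "different" trials and negated on "same"
#' trials, with the upper boundary mapped to the "Different" response.
#'
#' Sampling is adaptive Metropolis-within-Gibbs: per-cell random-walk
#' updates of the four parameters (proposal scales tuned toward 44%
#' acceptance during warmup and then frozen), conjugate Gibbs draws for the
#' group means, and random-walk updates on the log of the group SDs.
#' Nondecision times above a cell's minimum observed RT have zero
#' likelihood and are rejected automatically, which bounds each cell's
#' nondecision time just below its fastest retained trial.
#'
#' @param records Retained trial data.frame (see [filter_trials()]).
#' @param spec A [csddm_spec] object.
#' @return An object of class `csddm_fit`: posterior draws of the group
#'   means/SDs (`draws$mu`, `draws$sig`, indexed draw x parameter x
#'   condition) and person-condition parameters (`draws$theta`), the data
#'   mapping, and convergence diagnostics (split R-hat and effective sample
#'   size for every group-level scalar).  Nonconvergence is reported via
#'   `diagnostics$converged` and a warning, never an error.
#' @seealso [summary.csddm_fit()], [contrasts_csddm()], [posterior_predictive()]
#' @export
fit_csddm <- function(records, spec = csddm_spec()) {
  stopifnot(inherits(spec, "csddm_spec"))
  dat <- csddm_data(records)
  C <- length(dat$conds); ncell <- dat$ncell
  n_iter <- spec$warmup + spec$draws
  prior_mu <- list(spec$priors$mu_drift, spec$priors$mu_bias,
                   spec$priors$mu_boundary, spec$priors$mu_ndt)
  t0 <- proc.time()[["elapsed"]]

  # crude per-cell method-of-moments starts: drift from accuracy, ndt just
  # under the fastest trial, boundary from the mean decision time
  correct <- as.integer(dat$upper == (dat$sign > 0))
  acc0 <- as.numeric(tapply(correct, dat$cell, mean))
  v0 <- qnorm(pmin(pmax(acc0, 0.55), 0.98))
  tau0 <- pmax(0.05, dat$minrt - 0.08)
  mdt0 <- pmax(0.1, as.numeric(tapply(dat$rt, dat$cell, mean)) - tau0)
  a0 <- vapply(seq_along(v0), function(i) {
    agrid <- seq(0.5, 4, by = 0.05)
    edt <- agrid / (2 * max(v0[i], 0.2)) * tanh(agrid * max(v0[i], 0.2) / 2)
    agrid[which.min(abs(edt - mdt0[i]))]
  }, 0)

  run_chain <- function(chain) {
    set.seed(spec$seed * 1000L + chain)
    cc <- dat$cellcond
    theta <- rbind(
      drift = v0 + 0.2 * rnorm(ncell),
      bias_logit = if (spec$fix_bias) rep(0, ncell) else 0.1 * rnorm(ncell),
      boundary_log = log(a0) + 0.1 * rnorm(ncell),
      ndt = pmax(0.05, pmin(0.95 * dat$minrt, tau0 + 0.02 * rnorm(ncell))))
    mu <- matrix(0, 4, C)
    for (p in 1:4)
      mu[p, ] <- as.numeric(tapply(theta[p, ], cc, mean)) + 0.05 * rnorm(C)
    if (spec$fix_bias) mu[2, ] <- 0
    mu[4, ] <- pmax(0.05, mu[4, ])
    sig <- matrix(0.3, 4, C)
    scales <- matrix(0.15, 4, ncell)
    sig_scales <- matrix(0.3, 4, C)

    loglik <- function(th) wfpt_loglik_cells_cpp(
      dat$rt, dat$upper, dat$cell, dat$sign, th[1, ], exp(th[3, ]),
      stats::plogis(th[2, ]), th[4, ], dat$ncell, spec$eps)
    ll <- loglik(theta)
    stopifnot(all(is.finite(ll)))
    ndraw <- spec$draws
    mu_st <- array(NA_real_, c(ndraw, 4, C))
    sig_st <- array(NA_real_, c(ndraw, 4, C))
    th_st <- array(NA_real_, c(ndraw, 4, ncell))
    params <- if (spec$fix_bias) c(1L, 3L, 4L) else 1:4
    n_c <- tabulate(cc, C)

    # adaptive joint proposal (Haario-style): per-cell empirical covariance
    # of the updated parameters, refreshed periodically during warmup
    k <- length(params)
    m1 <- matrix(0, k, ncell); m2 <- array(0, c(k, k, ncell)); ncov <- 0L
    Lprop <- array(0, c(k, k, ncell)); have_L <- FALSE
    s_joint <- rep(1, ncell)
    asis_mu_sc <- matrix(0.05, 4, C); asis_sig_sc <- matrix(0.2, 4, C)

    for (it in seq_len(n_iter)) {
      gain <- if (it <= spec$warmup) min(0.25, 2 / sqrt(it)) else 0
      # person-condition updates, one parameter type at a time, all cells at once
      for (p in params) {
        prop <- theta
        prop[p, ] <- theta[p, ] + scales[p, ] * rnorm(ncell)
        ok <- if (p == 4L) prop[4, ] > 0 else rep(TRUE, ncell)
        llp <- loglik(prop)
        logr <- llp - ll +
          dnorm(prop[p, ], mu[p, cc], sig[p, cc], log = TRUE) -
          dnorm(theta[p, ], mu[p, cc], sig[p, cc], log = TRUE)
        logr[!ok | !is.finite(llp)] <- -Inf
        acc <- log(runif(ncell)) < logr
        theta[p, acc] <- prop[p, acc]
        ll[acc] <- llp[acc]
        if (gain > 0)
          scales[p, ] <- pmax(1e-3, scales[p, ] * exp(gain * ((acc) - 0.44)))
      }
      # joint per-cell update along the adapted covariance
      if (have_L) {
        prop <- theta
        z <- matrix(rnorm(k * ncell), k)
        for (ce in seq_len(ncell))
          prop[params, ce] <- theta[params, ce] +
            s_joint[ce] * (Lprop[, , ce] %*% z[, ce])
        ok <- prop[4, ] > 0
        llp <- loglik(prop)
        logr <- llp - ll
        for (p in params)
          logr <- logr + dnorm(prop[p, ], mu[p, cc], sig[p, cc], log = TRUE) -
            dnorm(theta[p, ], mu[p, cc], sig[p, cc], log = TRUE)
        logr[!ok | !is.finite(llp)] <- -Inf
        acc <- log(runif(ncell)) < logr
        theta[, acc] <- prop[, acc]
        ll[acc] <- llp[acc]
        if (gain > 0)
          s_joint <- pmax(0.05, s_joint * exp(gain * ((acc) - 0.25)))
      }
      # accumulate the empirical covariance during warmup
      if (it <= spec$warmup && it > 50) {
        ncov <- ncov + 1L
        thd <- theta[params, , drop = FALSE]
        m1 <- m1 + thd
        for (a in seq_len(k)) for (b in a:k)
          m2[a, b, ] <- m2[a, b, ] + thd[a, ] * thd[b, ]
        if (ncov >= 150 && it %% 25 == 0) {
          mbar <- m1 / ncov
          for (ce in seq_len(ncell)) {
            S <- matrix(0, k, k)
            for (a in seq_len(k)) for (b in a:k) {
              S[a, b] <- m2[a, b, ce] / ncov - mbar[a, ce] * mbar[b, ce]
              S[b, a] <- S[a, b]
            }
            diag(S) <- diag(S) + 1e-8
            Lc <- tryCatch(t(chol(S)), error = function(e) NULL)
            if (!is.null(Lc)) Lprop[, , ce] <- Lc * (2.38 / sqrt(k))
          }
          have_L <- TRUE
        }
      }
      # group means: conjugate normal given person-condition values
      for (p in params) {
        xs <- as.numeric(rowsum(theta[p, ], cc))
        v_post <- 1 / (n_c / sig[p, ]^2 + 1 / prior_mu[[p]][2]^2)
        m_post <- v_post * (xs / sig[p, ]^2 +
                              prior_mu[[p]][1] / prior_mu[[p]][2]^2)
        if (p == 4L) {
          mu[4, ] <- qtruncnorm0(runif(C), m_post, sqrt(v_post))
        } else {
          mu[p, ] <- rnorm(C, m_post, sqrt(v_post))
        }
      }
      # group SDs: random walk on log scale, half-normal prior
      for (p in params) {
        ss <- as.numeric(rowsum((theta[p, ] - mu[p, cc])^2, cc))
        prop <- sig[p, ] * exp(sig_scales[p, ] * rnorm(C))
        logr <- (-n_c * log(prop) - ss / (2 * prop^2) -
                   prop^2 / (2 * spec$priors$sd_scale^2) + log(prop)) -
          (-n_c * log(sig[p, ]) - ss / (2 * sig[p, ]^2) -
             sig[p, ]^2 / (2 * spec$priors$sd_scale^2) + log(sig[p, ]))
        acc <- log(runif(C)) < logr
        sig[p, acc] <- prop[acc]
        if (gain > 0)
          sig_scales[p, ] <- pmax(1e-3, sig_scales[p, ] * exp(gain * ((acc) - 0.44)))
      }
      # interleaved non-centered move: shift/rescale a condition's group
      # mean and SD with the standardised person deviations held fixed,
      # which decouples the group SD from the person-level random walk
      for (p in params) {
        raw <- (theta[p, ] - mu[p, cc]) / sig[p, cc]
        mu_p <- mu[p, ] + asis_mu_sc[p, ] * rnorm(C)
        sig_p <- sig[p, ] * exp(asis_sig_sc[p, ] * rnorm(C))
        prop <- theta
        prop[p, ] <- mu_p[cc] + sig_p[cc] * raw
        llp <- loglik(prop)
        dll <- as.numeric(rowsum(llp - ll, cc))
        pm <- prior_mu[[p]]
        logr <- dll +
          dnorm(mu_p, pm[1], pm[2], log = TRUE) -
          dnorm(mu[p, ], pm[1], pm[2], log = TRUE) +
          (-sig_p^2 + sig[p, ]^2) / (2 * spec$priors$sd_scale^2) +
          log(sig_p) - log(sig[p, ])
        bad_cell <- !is.finite(llp) | (p == 4L & prop[4, ] <= 0)
        logr[unique(cc[bad_cell])] <- -Inf
        if (p == 4L) logr[mu_p <= 0] <- -Inf
        acc <- log(runif(C)) < logr
        sel <- acc[cc]
        theta[p, sel] <- prop[p, sel]
        ll[sel] <- llp[sel]
        mu[p, acc] <- mu_p[acc]; sig[p, acc] <- sig_p[acc]
        if (gain > 0) {
          asis_mu_sc[p, ] <- pmax(1e-4, asis_mu_sc[p, ] * exp(gain * ((acc) - 0.25)))
          asis_sig_sc[p, ] <- pmax(1e-3, asis_sig_sc[p, ] * exp(gain * ((acc) - 0.25)))
        }
      }
      if (it > spec$warmup) {
        ix <- it - spec$warmup
        mu_st[ix, , ] <- mu; sig_st[ix, , ] <- sig; th_st[ix, , ] <- theta
      }
    }
    list(mu = mu_st, sig = sig_st, theta = th_st)
  }

  chains <- lapply(seq_len(spec$chains), run_chain)
  bind1 <- function(nm) {
    out <- do.call(abind1, lapply(chains, `[[`, nm))
    out
  }
  draws <- list(mu = bind1("mu"), sig = bind1("sig"), theta = bind1("theta"))
  dimnames(draws$mu) <- dimnames(draws$sig) <-
    list(NULL, ddm_param_names, paste0("v", dat$conds))
  chain_id <- rep(seq_len(spec$chains), each = spec$draws)

  diag <- group_diagnostics(draws, chain_id, spec)
  fit <- structure(list(draws = draws, chain = chain_id, data = dat,
                        spec = spec, diagnostics = diag,
                        runtime_s = proc.time()[["elapsed"]] - t0),
                   class = "csddm_fit")
  if (!diag$converged)
    warning(sprintf(
      "convergence diagnostics flagged %d group-level parameter(s) with split R-hat > %.3f",
      sum(diag$table$rhat > spec$rhat_threshold, na.rm = TRUE),
      spec$rhat_threshold), call. = FALSE)
  fit
}

abind1 <- function(...) {
  arrs <- list(...)
  d <- dim(arrs[[1]])
  out <- array(NA_real_, c(sum(vapply(arrs, function(a) dim(a)[1], 0)), d[2], d[3]))
  at <- 0
  for (a in arrs) { out[at + seq_len(dim(a)[1]), , ] <- a; at <- at + dim(a)[1] }
  out
}

# Split R-hat (Gelman et al.) and effective sample size (Geyer initial
# positive sequence) for a draws x chains matrix.
split_rhat <- function(x, chain) {
  halves <- unsplit(lapply(split(seq_along(chain), chain), function(ix) {
    h <- rep(1:2, each = ceiling(length(ix) / 2))[seq_along(ix)]
    h
  }), chain)
  g <- interaction(chain, halves)
  m <- tapply(x, g, mean); v <- tapply(x, g, var); n <- tapply(x, g, length)
  if (any(v < 1e-12, na.rm = TRUE) || var(x) < 1e-12) return(1)
  W <- mean(v); B <- var(m) * mean(n)
  sqrt((mean(n) - 1) / mean(n) + B / (W * mean(n)))
}

ess_geyer <- function(x, chain) {
  per <- vapply(split(x, chain), function(z) {
    n <- length(z)
    if (var(z) < 1e-12) return(n)
    a <- stats::acf(z, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
    s <- 0
    for (k in seq(1, length(a) - 1, by = 2)) {
      pair <- a[k] + a[k + 1]
      if (is.na(pair) || pair < 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }, 0)
  sum(per)
}

group_diagnostics <- function(draws, chain_id, spec) {
  params <- if (spec$fix_bias) c(1, 3, 4) else 1:4
  rows <- list()
  for (what in c("mu", "sig")) {
    a <- draws[[what]]
    for (p in params) for (c in seq_len(dim(a)[3])) {
      x <- a[, p, c]
      rows[[length(rows) + 1]] <- data.frame(
        quantity = what, parameter = ddm_param_names[p],
        condition = dimnames(a)[[3]][c],
        rhat = split_rhat(x, chain_id),
        ess = ess_geyer(x, chain_id), stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  list(table = tab,
       converged = length(unique(chain_id)) < 2 ||
         all(tab$rhat <= spec$rhat_threshold, na.rm = TRUE))
}

posterior_summary <- function(x) {
  ci <- unname(quantile(x, c(0.025, 0.975), type = 7))
  data.frame(mean = mean(x), sd = sd(x), ci_low = ci[1], ci_high = ci[2],
             credible = !(ci[1] <= 0 && ci[2] >= 0))
}

#' Marginal group-mean draws
#'
#' Per-draw average of condition-level group means over the conditions
#' matching a filter, the building block of the condition summaries and
#' contrasts (balanced-design marginalisation: unweighted mean of matching
#' cells within each posterior draw).
#'
#' @param fit A `csddm_fit`.
#' @param parameter One of `"drift"`, `"bias_logit"`, `"boundary_log"`,
#'   `"ndt"`.
#' @param where Named list of factor = level filters, e.g.
#'   `list(probe_type = "single_probe", urgency = "high_3000ms")`.
#' @return Numeric vector with one value per posterior draw.
#' @export
marginal_group_draws <- function(fit, parameter, where = list()) {
  p <- match(parameter, ddm_param_names)
  if (is.na(p)) stop("unknown parameter: ", parameter)
  info <- fit$data$cond_info
  keep <- rep(TRUE, nrow(info))
  for (f in names(where)) keep <- keep & info[[f]] == where[[f]]
  if (!any(keep)) stop("no fitted condition matches the filter")
  m <- fit$draws$mu[, p, keep, drop = FALSE]
  rowMeans(matrix(m, nrow = dim(m)[1]))
}

#' Condition-level posterior summaries
#'
#' For each contrasted parameter, the marginal group mean at both levels of
#' its focal factor, within each probe type, mirroring the layout of the
#' study's condition-summary table: drift by study time, logit bias by
#' change probability, log boundary by urgency.
#'
#' @param fit A `csddm_fit`.
#' @return A data.frame with one row per parameter x level x probe type and
#'   posterior mean, SD, central 95% credible interval and credibility
#'   flag (interval excludes 0).
#' @export
condition_summaries <- function(fit) {
  cm <- contrast_map()
  info <- fit$data$cond_info
  rows <- list()
  for (i in seq_len(nrow(cm))) {
    if (fit$spec$fix_bias && cm$parameter[i] == "bias_logit") next
    for (pt in unique(info$probe_type)) {
      for (lev in c(cm$manipulated[i], cm$baseline[i])) {
        flt <- setNames(list(pt, lev), c("probe_type", cm$factor[i]))
        ok <- tryCatch({
          d <- marginal_group_draws(fit, cm$parameter[i], flt); TRUE
        }, error = function(e) FALSE)
        if (!ok) next
        rows[[length(rows) + 1]] <- cbind(
          data.frame(parameter = cm$parameter[i], factor = cm$factor[i],
                     level = lev, probe_type = pt, stringsAsFactors = FALSE),
          posterior_summary(d))
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Posterior contrasts of the task manipulations
#'
#' The three manipulation contrasts, computed per posterior draw on the
#' marginal group means and summarised afterwards: study-time contrast on
#' drift (long - short), probability-of-change contrast on logit bias
#' (high - low), choice-urgency contrast on log boundary (high - minimal),
#' each within probe type.  A contrast is "credible" when its central 95%
#' credible interval excludes 0.
#'
#' @param fit A `csddm_fit`.
#' @return A data.frame with one row per available contrast x probe type.
#' @export
contrasts_csddm <- function(fit) {
  cm <- contrast_map()
  info <- fit$data$cond_info
  rows <- list()
  for (i in seq_len(nrow(cm))) {
    if (fit$spec$fix_bias && cm$parameter[i] == "bias_logit") next
    for (pt in unique(info$probe_type)) {
      d <- tryCatch({
        man <- marginal_group_draws(fit, cm$parameter[i],
          setNames(list(pt, cm$manipulated[i]), c("probe_type", cm$factor[i])))
        base <- marginal_group_draws(fit, cm$parameter[i],
          setNames(list(pt, cm$baseline[i]), c("probe_type", cm$factor[i])))
        man - base
      }, error = function(e) NULL)
      if (is.null(d)) next
      rows[[length(rows) + 1]] <- cbind(
        data.frame(parameter = cm$parameter[i],
                   contrast = paste0(cm$manipulated[i], " - ", cm$baseline[i]),
                   probe_type = pt, stringsAsFactors = FALSE),
        posterior_summary(d))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Person-level posterior parameter means
#'
#' Posterior means of the person-condition parameters, averaged over the
#' conditions in a grouping ("overall", or one probe type), one value per
#' person and parameter; the person-level inputs of the correlation
#' analysis.
#'
#' @param fit A `csddm_fit`.
#' @param grouping `"overall"`, `"whole_display"` or `"single_probe"`.
#' @return A data.frame with `participant_id` and one column per parameter.
#' @export
person_parameter_table <- function(fit,
                                   grouping = c("overall", "whole_display",
                                                "single_probe")) {
  grouping <- match.arg(grouping)
  info <- fit$data$cond_info
  keepc <- if (grouping == "overall") rep(TRUE, nrow(info))
           else info$probe_type == grouping
  th <- apply(fit$draws$theta, c(2, 3), mean)   # posterior mean per cell
  out <- data.frame(participant_id = fit$data$persons)
  for (p in seq_along(ddm_param_names)) {
    v <- rep(NA_real_, length(fit$data$persons))
    for (i in seq_along(fit$data$persons)) {
      sel <- fit$data$cellperson == i & keepc[fit$data$cellcond]
      v[i] <- mean(th[p, sel])
    }
    out[[ddm_param_names[p]]] <- v
  }
  out
}
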