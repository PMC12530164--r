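---
title: "Methods: a hierarchical diffusion model for ambulatory change detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a hierarchical diffusion model for ambulatory change detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Brief smartphone change-detection sessions produce choice + response-time
data that summary scores (accuracy, mean RT) compress too aggressively:
speed–accuracy trade-offs, response biases induced by unequal trial
compositions, and encoding/motor overhead all end up in the same numbers.
`csddm` fits a drift diffusion model (DDM) instead, separating the rate of
evidence accumulation (drift δ), the evidence threshold (boundary
separation α), the starting-point bias toward one response (β), and
nondecision time (τ). The package covers the full workflow for a
within-person 2×2×2×2 factorial design — study time × probability of
change × choice urgency × probe type, i.e. 16 task versions played over 8
days — from synthetic-cohort simulation through preprocessing, fitting,
posterior predictive checking and covariate correlation.

## Likelihood

A trial is modelled as a unit-diffusion Wiener process on evidence
space $[0, \alpha]$, started at $\alpha\beta$, with drift $\pm\delta$ and
absorbed at either boundary; absorption time plus $\tau$ is the RT. The
joint density of (RT, boundary) is the first-passage-time density, which
has two classical series representations — one converging quickly for
small scaled times, one for large. Each evaluation picks the
representation needing fewer terms at truncation error $10^{-7}$ (the
sampler's default; $10^{-10}$ in validation tests), after the common
rescaling to a unit boundary. The upper-boundary density is obtained from
the lower by reflection ($\delta \to -\delta$, $\beta \to 1-\beta$). Three
properties are enforced by tests rather than assumed: the density
integrates to 1 over both boundaries (within $10^{-4}$, in practice
$10^{-13}$); its upper-boundary mass equals the closed-form absorption
probability $(1 - e^{-2\delta\alpha\beta})/(1 - e^{-2\delta\alpha})$; and
$10^5$ draws from the production sampler stay within Kolmogorov–Smirnov
distance 0.01 of the numerically integrated CDF.

Two conventions worth making explicit:

* **Scaling.** The within-trial diffusion coefficient is fixed at 1 with
  time in seconds (RTs are converted from milliseconds on entry). Some DDM
  literatures use 0.1; boundary and drift values differ by that factor.
* **Zero mass before τ.** `wfpt_logdensity` returns $-\infty$ for
  $t \le \tau$ instead of raising an error, so the likelihood is defined
  for every observed RT and data cleaning stays in the preprocessing
  layer, not the likelihood.

**Sampling trials.** The production sampler is exact: the boundary is
drawn from the closed-form absorption probability and the decision time by
inverting the numerically integrated conditional CDF on a quadratically
spaced grid (4096 points, extended until the unaccounted tail mass is
below $10^{-6}$). A fixed-step Euler–Maruyama simulator
(`sample_trials_em`) is kept purely as an independent cross-check in the
test suite; its $O(\sqrt{dt})$ discretisation bias makes it unsuitable for
production and bounds how tightly the cross-check can be asserted.

## Hierarchical model

Every person × version cell carries its own $(\delta, \log\alpha,
\mathrm{logit}\,\beta, \tau)$. The transformed scales make the group-level
normal assumption coherent: back-transformed boundaries are always
positive and biases always in (0,1). Cell values are drawn from
condition-level group distributions,
$\theta_{ic} \sim N(\mu_{c}, \sigma_{c})$ per parameter, with no
constraints tying the 16 conditions together — condition effects are read
off afterwards as contrasts, not imposed.

**Response coding.** The upper boundary is the *Different* response.
Stimulus coding is used: one drift magnitude per cell, positive on
*different* trials, negated on *same* trials. This is a deliberate design
choice — under accuracy coding a condition-level bias toward *Different*
would be meaningless, and the probability-of-change manipulation targets
exactly that bias. The restricted model with β fixed at 0.5
(`fix_bias = TRUE`) exists for misspecification analyses.

**Priors** (weakly informative, all configurable): group means
$N(0, 3^2)$ for drift, $N(0, 1.5^2)$ for logit bias and log boundary,
$N(0.3, 0.3^2)$ truncated at 0 for τ (seconds); all group SDs
half-normal(1). With 60 trials per cell the likelihood dominates these
comfortably; a prior-dominance test confirms that extremely tight priors
pin the posterior, i.e. the priors enter the joint density correctly.

**Nondecision-time support.** A cell's τ cannot exceed its fastest
retained RT — beyond it the likelihood is exactly zero, so such proposals
are rejected automatically. This is a numerical guard implied by the
likelihood, not an extra modelling assumption.

## Sampler

All parameters are estimated jointly in one MCMC run per chain:

1. *Per-cell random-walk Metropolis*, one parameter type at a time across
   all cells simultaneously (the cells are conditionally independent given
   the group level), proposal scales adapted toward 44% acceptance during
   warmup and frozen afterwards.
2. *Per-cell joint proposals* along the empirical posterior covariance of
   the four parameters (Haario-style adaptive Metropolis, covariance
   refreshed every 25 warmup iterations), because drift, boundary and τ
   are strongly correlated a posteriori and single-site moves mix slowly
   through that ridge.
3. *Conjugate Gibbs* draws for the group means (truncated-normal draw for
   the τ mean).
4. *Random-walk moves on log σ* for the group SDs, and — critically — an
   *interleaved non-centered step*: propose shifting/rescaling a
   condition's $(\mu_c, \sigma_c)$ with the standardised person deviations
   held fixed. The centered parameterisation alone leaves the group SDs
   stuck in the funnel when true between-person spread is small; the
   interleaving restores mixing there (an ancillarity–sufficiency
   interleaving scheme).

Defaults: 4 chains × (1000 warmup + 1000 draws), split-R̂ threshold 1.01
and ESS reported for every group-level scalar. Nonconvergence warns and
returns the draws rather than erroring, so diagnostics failures are
visible but recoverable. Initial values are crude per-cell
method-of-moments guesses (accuracy → drift, fastest RT → τ, mean decision
time → boundary), jittered per chain.

**Marginal summaries and contrasts.** Condition summaries marginalise the
group means over the non-focal factors by the unweighted per-draw mean of
the matching cells (the design is balanced), then summarise. The three
manipulation contrasts — drift: long − short study time; logit bias: high
− low change probability; log boundary: high − minimal urgency — are
computed per draw within probe type and declared credible when the central
95% interval excludes 0. Per-draw marginalisation (rather than refitting
per margin) keeps the full joint uncertainty.

## Synthetic cohorts

The generator is first-class, tested code: it defines the study conditions
every downstream stage is validated under. Defaults emulate the reference
ambulatory design: 68 participants; ages from a truncated normal, mean 49,
SD 14, range 24–80; 16 versions × 60 trials over 8 days, two per day,
orderings drawn from 3 fixed schedules; exact trial compositions (48/12
*different*/*same* in high-change versions, 30/30 otherwise); deadline
censoring at 3000/10,000 ms recorded as unresponded trials; whole-session
missingness at 8.45% (matching the observed unrecorded-trial rate of such
designs); and a 0.09% contaminant rate with RTs drawn below 200 ms or
above 7000 ms.

Ground-truth group means default to magnitudes typical of fitted condition
summaries for this task family (e.g. single-probe drift ≈ 0.9, logit-bias
shift +0.15 under high change probability, log-boundary shift −0.05 under
urgency), so recovery experiments exercise realistic effect sizes.
Between-person SDs are not published quantities; the defaults (0.45 drift,
0.22 logit bias, 0.22 log boundary, 0.07 s τ) were chosen once by working
backwards from contrast posterior SDs of ≈0.02 at n = 68 — the total
person-cell spread consistent with those — and from typical individual
differences in ageing samples for drift. The age–drift link is built by
residualisation (drift deviation = λ·standardised age + orthogonal noise,
shared across conditions), so the configured correlation holds exactly in
sample.

What the generator does *not* emulate — and what passing recovery tests
therefore cannot certify about real data: strategy use (e.g. encoding only
2 of 3 shapes), practice and time-of-day effects, RT autocorrelation
within sessions, non-normal person effects, and any drift–boundary
trade-off correlation at the person level.

## Preprocessing semantics

"Faster than 200 ms and slower than 7000 ms" is read as strict
inequalities: RTs exactly at the bounds are retained. Deadline exclusion
(unresponded trials) is applied before the RT bounds so nothing is
double-counted, and percentages use scheduled trials (participants × 960)
as the denominator throughout. A version counts as completed when at least
one of its trials was recorded. The exclusion report enforces its own
conservation identities (scheduled = recorded + unrecorded; retained =
recorded − deadline − out-of-bounds) and filtering is idempotent.

## Posterior predictive checks

For each of `n_sim` posterior draws (default 6000 at study scale, 200 in
scaled-down checks; draws are resampled with replacement if `n_sim`
exceeds the stored draws) a full dataset is simulated under the observed
design — same cells, trial counts and truth compositions. Simulated RTs
beyond the condition deadline are flagged and dropped by the check exactly
as observed deadline trials are dropped by preprocessing, which preserves
per-cell counts while honouring censoring. RT quantiles at levels
{0.1, 0.3, 0.5, 0.7, 0.9} (the standard RT-quantile convention; linear
interpolation of order statistics, R type 7, for bit-stable results) are
compared per condition × correctness against the across-simulation median
and central 95% band; cells with fewer than 5 observed trials are flagged
and skipped as unstable. The coverage score — the fraction of observed
quantiles inside their bands — is ≥ 0.90 on well-specified synthetic data
and strictly degrades when a no-bias model is fitted to strongly biased
data, which is the operational content of "the model fits well".

## Bayesian correlations

Person-level parameter values are posterior means of the person-condition
parameters averaged over the conditions in the grouping (overall, or one
probe type); propagating full posterior uncertainty into the correlation
is out of scope. The correlation analysis is exact, not approximate: the
sampling density of the Pearson r given the population correlation ρ
(hypergeometric form, evaluated by direct series) is integrated over a
symmetric stretched-beta prior on ρ (width 1 — a uniform prior, the
common GUI default) by adaptive quadrature split at the likelihood peak;
the null model fixes ρ = 0. Credible intervals come from the normalised
posterior on a 4001-point grid. |r| is clamped at $1 - 10^{-6}$ for the
numerics only (the evidence is unbounded there). A fixed fine-grid
trapezoid oracle, re-derived independently in the tests, agrees to better
than 3 significant figures at n = 68. Evidence labels follow the
conventional bands (3–10 moderate, 10–30 strong, 30–100 very strong,
>100 extreme), with reciprocal bands suffixed "(null)". No multiplicity
adjustment is applied across the scan.

## Problem sizes used by the tests

Scaled-down sizes were chosen so the full suite runs comfortably on one
CPU: recovery uses 10 repetitions of 20 persons × 4 single-probe
conditions × 60 trials with 2 chains × (700 + 700) draws (pooled 95%
credible-interval coverage ≥ 0.90 over all group means; null contrasts
non-credible in ≥ 90%; detection of the +0.15 bias shift is asserted at
the realistic size of 68 participants); predictive checks use 8 persons ×
2 conditions × 80 trials with 200 predictive datasets; the degenerate
zero-variance check uses 24 persons × 120 trials, where measurement noise
no longer masquerades as between-person spread. Sampler validation uses
$10^5$ draws; Euler–Maruyama cross-checks use $2 \times 10^4$ paths at
$dt = 10^{-4}$ s.

## Known limitations

* No across-trial variability parameters (trial-to-trial drift/start/τ
  variability of the full Ratcliff model): four parameters per cell only.
* Deadline censoring is handled by exclusion, as in the emulated design,
  not by truncation-corrected likelihood; with heavy censoring this biases
  drift upward and boundary downward.
* Metropolis-within-Gibbs mixes more slowly than gradient-based samplers;
  at demo-scale settings a few group-SD R̂ values can sit slightly above
  1.01 (reported, not hidden).
* The correlation stage uses posterior means, understating person-level
  uncertainty.
* Collapsing boundaries, urgency gating, and leaky/Lévy accumulation are
  out of scope.
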