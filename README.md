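# csddm — hierarchical drift diffusion modelling for ambulatory change-detection data

`csddm` analyses response time (RT) and accuracy data from
smartphone-administered visual working-memory change-detection tasks (the
"Color Shapes" paradigm: study an array of coloured abstract shapes, then
judge whether a test array shows the *same* colour–shape bindings or a
*different* one). It is aimed at cognitive and ageing researchers who run
brief, repeated ambulatory assessments — up to 68 participants playing 16
task versions of 60 trials over 8 days — and want latent cognitive
parameters rather than mean scores.

## The model

Each decision is modelled as a one-dimensional Wiener diffusion between two
absorbing boundaries: evidence accumulates from the starting point αβ at
mean rate δ (with unit diffusion coefficient and time in seconds) until it
hits the upper boundary α ("respond *Different*") or the lower boundary 0
("respond *Same*"); the observed RT adds a nondecision time τ for encoding
and motor execution. The four parameters per person × task-version cell:

| symbol | parameter | scale used for modelling |
|---|---|---|
| δ | drift rate | natural |
| α | boundary separation | log |
| β | initial bias (start point, in (0,1)) | logit |
| τ | nondecision time (s) | natural |

Drift is *stimulus-coded*: the cell-level drift magnitude enters positively
on *different* trials and negated on *same* trials, so β measures a genuine
response bias toward *Different*. Person-condition values are tied together
by condition-level normal group distributions on the sampling scales, and
everything is estimated jointly by MCMC (adaptive Metropolis-within-Gibbs
with joint empirical-covariance proposals and an interleaved non-centered
step; split-R̂ and effective sample sizes are reported on every group-level
parameter). The likelihood is the exact Wiener first-passage-time density,
evaluated through its small-time and large-time series expansions.

The three task manipulations map onto posterior *contrasts* computed per
draw on marginal group means: study time → drift, probability of change →
logit bias, choice urgency → log boundary, each within probe type, with a
contrast called credible when its central 95% credible interval excludes 0.
Person-level posterior means can then be correlated with covariates such as
age through an exact Bayesian Pearson correlation (stretched-beta prior,
Bayes factor by quadrature).

## Worked example

```r
library(csddm)
# simulate a small ambulatory cohort: 12 participants, the four
# single-probe versions crossing change probability x urgency
cfg <- cohort_config(n_participants = 12, conditions = c(9, 11, 13, 15),
                     seed = 42)
cohort <- generate_cohort(cfg)
flt <- filter_trials(cohort$trials, expected_per_participant = 240)
print(flt$report)
#> Trial accounting (% of scheduled):
#>   scheduled              2880  (100.00%)
#>   recorded               2640  ( 91.67%)
#>   unrecorded              240  (  8.33%)
#>   deadline_excluded        18  (  0.62%)
#>   rt_bound_excluded         4  (  0.14%)
#>   retained               2618  ( 90.90%)

fit <- fit_csddm(flt$retained,
                 csddm_spec(chains = 2, warmup = 1000, draws = 1000, seed = 1))
summary(fit)
#> Marginal condition summaries (group means, sampling scales):
#>     parameter      factor           level   probe_type   mean    sd ci_low ci_high credible
#>         drift  study_time     short_500ms single_probe  0.904 0.079  0.746   1.066     TRUE
#>    bias_logit change_prob         high_80 single_probe  0.040 0.064 -0.085   0.172    FALSE
#>    bias_logit change_prob          low_50 single_probe -0.030 0.071 -0.176   0.107    FALSE
#>  boundary_log     urgency     high_3000ms single_probe  0.647 0.041  0.564   0.723     TRUE
#>  boundary_log     urgency minimal_10000ms single_probe  0.712 0.056  0.600   0.827     TRUE
#>
#> Manipulation contrasts (manipulated - baseline):
#>     parameter                      contrast   probe_type   mean    sd ci_low ci_high credible
#>    bias_logit              high_80 - low_50 single_probe  0.070 0.095 -0.116   0.262    FALSE
#>  boundary_log high_3000ms - minimal_10000ms single_probe -0.065 0.070 -0.207   0.070    FALSE
```

The accounting shows the retention pipeline (8.3% of scheduled trials lost
to whole-session missingness, 18 trials censored at the 3000 ms response
deadline, 4 contaminant RTs outside the 200–7000 ms bounds). The fit
recovers the generating group means (e.g. drift 0.90 against a generating
value of 0.88); at 12 participants the ±0.15-scale bias shift is visible
(contrast +0.07) but not yet credible — power arrives at realistic sample
sizes, which the test suite checks at 68 participants. Convergence warnings
at this demo scale disappear with the default 4 × (1000 + 1000) sampler
settings.

Correlating a person-level parameter with age:

```r
pearson_bf(cohort$truth$ages, person_parameter_table(fit)$drift)
#> Pearson r = -0.351 (n = 12), BF10 = 0.6247 [anecdotal (null)], 95% CI (-0.702, 0.269)
```

A full pipeline run (simulate → preprocess → fit → posterior predictive
check → correlations → report, with every artifact written as CSV/JSON plus
a manifest) is one call:

```r
run_pipeline(run_config(out_dir = "demo_run", seed = 1))
```

or from a shell, `Rscript inst/scripts/csddm.R all --out demo_run --seed 1`.

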