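# ptdisc

Past temporal discounting (PTD) is the decline, over elapsed time, of the
affect intensity elicited by recalling a past event: happy memories lose
their glow and painful ones their sting as the event recedes. `ptdisc` is
an R package plus analysis workflow for the longitudinal design used to
measure PTD — participants recall three positive and three negative recent
events and rate, at eight follow-ups spaced four days apart, the affect
each recollection elicits on a −100..100 scale — and for testing how
individual discounting rates relate to mental health. It is written for
quantitative psychologists and biostatisticians working with hierarchical
growth models of affect.

The core model, per valence, is a Bayesian mixed-effects quadratic
trajectory over time distance *t* (days since the event, 4–63 here):

    A_ijt = (b0 + u0_i + e0_ij) + (b1 + u1_i) t + (b2 + u2_i) t² + ε_ijt

with participant deviations (u0, u1, u2), event-within-participant
intercepts e0, and Gaussian residuals, sampled by MCMC (JAGS) and checked
with rank-normalized split R-hat and bulk-ESS. Each participant's
discounting rate is the area under their scaled predicted-affect curve
(time mapped to [0, 1] via (t−4)/59, affect divided by its day-4 value):
AUC = 1 means no discounting, smaller means faster discounting, and
negative values (a sign-flipped curve) trigger exclusion. The PTD bias —
normalized AUC-positive minus normalized AUC-negative — is positive when
negative events fade faster, the fading-affect-bias direction. Inference
uses permutation tests (sign-flip paired t with d_z = t/√n; Spearman with
permuted margins) and standardized multiple regressions of five
questionnaire totals (WEMWBS, BDI, TAI, PSS, RRS) on the two rates.

No participant-level dataset for this design is public, so the package
ships a synthetic-cohort generator (`simulate_cohort()`) whose defaults
are the study conditions (210 participants, 3 + 3 events, 8 waves, the
published population trajectories) with known ground truth, and every
stage is validated by parameter recovery against it. See the vignette
(`vignettes/past-temporal-discounting.Rmd`) for the model, priors,
generator assumptions and limitations.

## Worked example

```r
library(ptdisc)

cfg  <- cohort_config(seed = 20260923)       # the study design, defaults
sim  <- simulate_cohort(cfg)                 # panel + scale totals + truth
mc   <- mcmc_config(n_chains = 3, n_iterations = 1500, n_warmup = 500, seed = 101)
fpos <- fit_discount_model(sim$panel, "positive", mc)
fpos
#> Bayesian mixed-effects quadratic discounting model (positive events)
#>   210 participants, 630 events, 5040 observations; 3 chains x 1000 kept draws
#>   Intercept   68.842  95% HPDI [66.318, 71.444]  R-hat 0.999  ESS 2913
#>   Time        -0.824  95% HPDI [-0.956, -0.694]  R-hat 1.000  ESS 2737
#>   Time^2       0.007  95% HPDI [0.005, 0.009]  R-hat 1.000  ESS 2722
```

The affect elicited by recalling positive events starts near 69 scale
points and declines by ~0.8 points per day early on, decelerating (the
positive quadratic term); the generating values (67.806, −0.816, 0.007)
sit inside all three intervals. Scoring and comparing the two valences:

```r
fneg <- fit_discount_model(sim$panel, "negative", mcmc_config(
          n_chains = 3, n_iterations = 1500, n_warmup = 500, seed = 102))
rec  <- score_cohort(fpos, fneg)
#> scored 210 participants; excluded 0 (negative AUC: 0, abnormal pattern: 0)
inc  <- rec[rec$included, ]
paired_permutation_test(inc$auc_pos, inc$auc_neg, n_perm = 1000, seed = 31)
#> paired t = 2.074, permutation p = 0.03996 (1000 permutations, n = 210), Cohen's d = 0.143
```

Mean AUC-positive (0.773) exceeds mean AUC-negative (0.753): negative
events discount faster — the fading affect bias. The mental-health battery
(`run_mental_health_models(rec, sim$scales)`) then returns the tidy table
of standardized betas, e.g. well-being rising with slow positive-event
discounting (β = 0.221, 95% CI [0.084, 0.358] on this cohort).

The numbered drivers under `analysis/` run the same workflow end to end
(`01_simulate.R` … `05_power.R`), writing tables under `results/`.

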