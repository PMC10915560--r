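---
title: "Modelling past temporal discounting of recalled affect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling past temporal discounting of recalled affect}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Past temporal discounting (PTD) is the decline, over elapsed time, of the
affect intensity elicited by recalling an autobiographical event: the joy of
recalling a holiday and the sting of recalling a failure both fade as the
event recedes. `ptdisc` implements a complete, testable pipeline for the
longitudinal design used to measure PTD: participants recall three positive
and three negative recent events (each at most a month old) and rate, at
eight follow-ups spaced four days apart, the affect each recollection
elicits on a −100..100 visual-analog scale. Because the elapsed time
("time distance") between an event and a rating occasion ranges over 4–63
days across events and waves, the design separates the effect of time from
the effect of the events themselves.

No participant-level dataset is publicly available for this design, so the
package is organised around a synthetic-cohort generator whose structure
matches the analysis assumptions; every downstream stage is exercised
against cohorts with known ground truth.

## The model

For each valence separately, the affect rating of participant *i*, event
*j*, at time distance *t* (raw days) is modelled as

$$A_{ijt} = (b_0 + u_{0i} + e_{0ij}) + (b_1 + u_{1i})\,t + (b_2 + u_{2i})\,t^2 + \varepsilon_{ijt},$$

with participant deviations $(u_{0i}, u_{1i}, u_{2i})$ drawn from a 3×3
covariance, event intercept deviations $e_{0ij}$ nested within
participants, and Gaussian residuals. Time is entered in raw days, so the
intercept is the affect intensity at the event day; the quadratic term
captures the deceleration of discounting. The two valences are fit as two
separate models.

Posterior sampling is MCMC via JAGS (`rjags`), with the block conjugate
samplers of the `glm` module — essential for mixing, because $t$ and $t^2$
are strongly collinear over 4–63. Priors are weakly informative and
scale-adapted: Normal(0, 10·SD(y)) on the fixed effects, half-Student-t(3,
SD(y)) on the event and residual SDs, and a weakly informative Wishart
(df = 4, data-scaled) on the participant random-effect precision matrix —
the standard BUGS-family prior for a small covariance; its df = d + 1 choice
keeps the implied marginal correlations near-uniform. A `prior_scale`
multiplier in `mcmc_config()` supports sensitivity analysis; doubling all
prior scales moves the fixed-effect posterior means by well under 5% at the
default cohort size (asserted in the test suite).

Convergence is judged by rank-normalized split R-hat and bulk effective
sample size, implemented in the package (`rhat()`, `ess_bulk()`) with
pass/warn thresholds at 1.01 and 1000. A fixed-effect R-hat of 1.05 or more
raises an error — the same criterion by which a cubic specification of this
model is rejected as unusable (the cubic degree is exposed via
`mcmc_config(degree = 3)` but is not part of the supported analysis).
Variance components whose true value sits at the boundary (for instance in
cohorts generated without random effects) can show spuriously elevated
split R-hat while the chains are fine; they warn rather than error, and
their SDs are truncated at 10⁻⁶·SD(y) so that degenerate, noiseless inputs
keep a finite likelihood.

## Scoring discounting rates

A participant's discounting rate is the normalized area under their
predicted-affect curve:

1. the individual path is the posterior-mean fixed effects plus the
   posterior means of that participant's deviations (event deviations
   average out) — `extract_individual_paths()`;
2. the path is evaluated on integer days 4..63 — `predict_affect_grid()`;
3. time is scaled to [0, 1] by subtracting 4 and dividing by 59, and affect
   is divided by its day-4 value so every curve starts at exactly 1 —
   `scale_discount_curve()`. Dividing by a negative first value (negative
   events) yields a positive scaled curve naturally; no absolute values are
   taken anywhere;
4. the area under the scaled curve is computed by the composite trapezoid
   rule — `auc_trapezoid()`. AUC = 1 means no discounting; smaller values
   mean faster discounting; a negative value means the curve crossed zero
   and its sign-flipped tail dominates, which violates the definition of a
   discounting rate and excludes the participant (`score_cohort()`).

For a quadratic path the scaled AUC has a closed form,
`auc_exact_quadratic()`, which serves as the analytic oracle: on the
60-point grid the trapezoid error is bounded by $|b_2| / (6\,v(4))$ and the
two methods agree within 2·10⁻⁴ for any path drawn from the generative
model. Scoring uses the grid-and-trapezoid route because it matches the
predict-then-integrate procedure and generalises to non-quadratic paths; a
per-draw variant (score every posterior draw's path, then average) is
available via `screen_config(per_draw = TRUE)`.

The PTD bias is the difference between normalized AUC-positive and
AUC-negative (`ptd_bias()`). "Normalized" is not further specified in the
source analysis; the package z-scores over included participants by
default (min-max is available), since z-scoring makes the bias location-
and scale-free in both components. Positive bias means negative events
discount faster — the fading-affect-bias (FAB) direction.

The original study additionally excluded two participants for
"significantly abnormal discounting patterns" under a supplementary
criterion that is not publicly available. `screen_config(abnormal_screen =
TRUE)` provides a clearly-labelled stand-in — flag a participant whose mean
rating sign contradicts the event valence in at least half the waves — and
is off by default for synthetic cohorts.

## The synthetic cohort generator

`cohort_config()` holds every generative choice; the defaults are the study
conditions:

| parameter | default | basis |
|---|---|---|
| participants | 210 | reported final sample |
| events | 3 per valence | study design |
| waves | 8, every 4 days | study design |
| event age at baseline | 0–31 days | "past month" |
| fixed effects (positive) | (67.806, −0.816, 0.007) | published estimates |
| fixed effects (negative) | (−51.569, 0.683, −0.006) | published estimates |
| participant RE SDs | (10, 0.15, 0.002) | plausible; not printed |
| event intercept SD | 8 | plausible; not printed |
| residual SD | 12 | plausible; not printed |
| cross-valence intercept corr. | 0.4 | plausible; not printed |
| encoding intensity | trunc. normal ≥ 35 | inclusion rule |

The random-effect and residual spreads are **unvalidated**: the source
analysis does not print its variance components, so these values were
chosen once to give spaghetti-plot spread and AUC dispersion of the right
order, and are documented as such. Two consequences worth knowing:

* the per-participant AUC spread they induce (SD ≈ 0.08–0.10) is smaller
  than the observed SD ≈ 0.25, so effect sizes that depend on that spread
  (for example the paired AUC comparison) come out somewhat larger per
  cohort than observed;
* only the intercept deviations are coupled across valences. The coupling
  is applied in the affect-*magnitude* direction — a trait for strong
  affect strengthens the initial intensity of both valences, pushing the
  two intercepts apart since they have opposite signs — because coupling
  the raw intercepts makes the two AUC scores correlate *negatively*
  downstream. With intercepts-only coupling the induced rate correlation is
  positive but weak; reproducing the observed rho ≈ 0.36 would require
  coupling the slope deviations too, which the generator deliberately does
  not assume.

Ratings are clipped to the −100..100 scale bounds rather than sampled from
a truncated distribution; clipping is rare at the defaults (≈ 0.2% of
ratings) and the count is logged and returned, so a configuration that
clips heavily is visible immediately. Mental-health scale totals (WEMWBS,
BDI, TAI, PSS, RRS) are generated from a latent outcome
$\gamma_{pos} z(\mathrm{AUC}^{true}_{pos}) + \gamma_{neg}
z(\mathrm{AUC}^{true}_{neg}) + e$ with the residual SD auto-completed to
unit latent variance, then mapped affinely into each instrument's range and
rounded; the default $\gamma$ follow the published effect pattern.
Because the generator links scales to *true* AUCs through a linear model
with Gaussian noise, passing recovery tests shows the pipeline estimates
what the generator encodes — it does not validate the linearity, the
Gaussian noise, or the absence of confounding in real questionnaire data.
Dropout is not simulated (the analysed sample is completers-only).

## Inference battery

`paired_permutation_test()` compares AUC-positive and AUC-negative with a
paired t statistic whose null is built by sign-flipping the paired
differences (the standard scheme for paired designs; the alternative,
label permutation, is equivalent here). `spearman_permutation()` permutes
one margin. Both report two-sided p-values with the add-one correction
`(#{|stat*| ≥ |stat|} + 1)/(B + 1)`, so p is never exactly zero, and are
reproducible given a seed. The paired effect size uses the d_z convention
d = t/√n — the only convention consistent with the published triple
(t = 1.93, n = 208, d = 0.134). `standardized_regression()` z-scores
outcome and predictors and fits OLS; its coefficients equal the
correlation-matrix closed form to numerical precision (asserted against
that oracle). `run_mental_health_models()` applies no multiple-testing
correction, matching the per-outcome reporting convention of the source
analysis, and says so in its output.

`power_simulation()` estimates design power by simulate-and-refit. The
default refitter is deliberately frequentist and fast — per-participant OLS
quadratics followed by a one-sample t-test on the linear coefficients —
because a full Bayesian refit per simulation would be wasteful; an
lme4/lmerTest mixed-model refitter is available for spot checks and agrees
with the OLS route on easy cases. At the default generative settings the
design's power to detect both valences' linear time effects is effectively
1 at α = 0.05 (200 simulations; the published analysis reports 96.5% and
93.8% under its own, unprinted variance components, so only the
"comfortably above 0.9" conclusion transfers).

## Numerical choices and degenerate inputs

* HPDI: shortest contiguous window over the sorted draws containing
  ⌈prob·n⌉ points; appropriate for unimodal posteriors, and verified
  against a brute-force window search.
* JAGS chains get explicit per-chain RNG seeds derived from the
  configuration seed, so fits are bit-reproducible; OLS coefficients seed
  the chains to keep early adaptation away from flat regions.
* `scale_discount_curve()` errors when the day-4 prediction is exactly 0
  (the curve cannot be normalized); `score_cohort()` surfaces this as an
  exclusion.
* Analysis problem sizes: the shipped drivers and the acceptance protocol
  use 3 chains × 1500 iterations (500 warm-up) for the full 210-participant
  design (about 30 s per valence), which leaves fixed-effect bulk-ESS near
  3000; the interactive default (`mcmc_config()`) is 4 × 4000 with 2000
  warm-up. The slowest-mixing quantities are the tiny quadratic RE variance
  and the event-intercept SD, which can sit below the ESS > 1000 threshold
  at reduced draws and trigger the corresponding warning.

## Known limitations

* Variance components are plausible stand-ins, not estimates; quantities
  that depend on them (AUC dispersion, paired effect size, the rate
  correlation) match the observed analysis only in direction and order of
  magnitude.
* The event-level random effects are intercept-only by default; eight
  observations per event cannot support event-level slopes robustly.
* The abnormal-pattern screen is a stand-in for an unavailable criterion.
* The permutation scheme for the paired test (sign-flips) and the bias
  normalization (z-score) are reasonable conventions where the source
  analysis is silent; both are configurable or documented where they
  matter.
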