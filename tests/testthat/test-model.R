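test_that("mcmc settings are validated", {
  expect_error(mcmc_config(n_chains = 1), "n_chains")
  expect_error(mcmc_config(n_warmup = 4000, n_iterations = 4000), "n_warmup")
  expect_error(mcmc_config(degree = 4), "degree")
  expect_error(mcmc_config(prior_scale = 0), "prior_scale")
  m <- mcmc_config()
  expect_equal(c(m$n_chains, m$n_iterations, m$n_warmup), c(4, 4000, 2000))
})

test_that("noiseless panel recovers the generating polynomial almost exactly", {
  cfg <- noiseless_config(n = 20)
  sim <- suppressMessages(simulate_cohort(cfg))
  mc <- mcmc_config(n_chains = 2, n_iterations = 700, n_warmup = 300,
                    n_adapt = 300, seed = 9)
  fit <- suppressWarnings(fit_discount_model(sim$panel, "positive", mc))
  b <- colMeans(fit$B)
  expect_true(all(abs(b - table1_pos) / abs(table1_pos) < 1e-3))
})

test_that("with random effects off, the posterior matches pooled OLS", {
  cfg <- cohort_config(n_participants = 30, re_sd_participant = c(0, 0, 0),
                       re_sd_event = 0, residual_sd = 10,
                       cross_valence_corr = 0, seed = 12)
  sim <- suppressMessages(simulate_cohort(cfg))
  mc <- mcmc_config(n_chains = 2, n_iterations = 900, n_warmup = 400,
                    n_adapt = 300, seed = 10)
  fit <- suppressWarnings(fit_discount_model(sim$panel, "positive", mc))
  rows <- sim$panel[sim$panel$valence == 1, ]
  ols <- unname(coef(lm(affect_rating ~ time_distance_days +
                          I(time_distance_days^2), rows)))
  b <- colMeans(fit$B)
  psd <- apply(fit$B, 2, sd)
  expect_true(all(abs(b - ols) < 2 * psd))
})

test_that("fit summary mirrors the population-parameter table", {
  fit <- small_fit_pos()
  expect_s3_class(fit, "ptd_fit")
  fx <- fit$summary[fit$summary$parameter %in% c("Intercept", "Time", "Time^2"), ]
  expect_equal(nrow(fx), 3)
  expect_true(all(c("estimate", "hpdi_low", "hpdi_high", "rhat", "ess") %in% names(fx)))
  expect_true(all(fx$hpdi_low <= fx$estimate & fx$estimate <= fx$hpdi_high))
  # recovery at the small-cohort scale: truth inside the 95% HPDI
  expect_true(all(fx$hpdi_low <= table1_pos & table1_pos <= fx$hpdi_high))
  expect_error(fit_discount_model(small_cohort()$panel[0, ], "positive"),
               "no rows")
})

test_that("marginal effect curve is the fixed-effect polynomial", {
  fit <- small_fit_pos()
  mec <- marginal_effect_curve(fit)
  b <- colMeans(fit$B)
  # linearity of expectation: mean curve equals the polynomial at the
  # posterior-mean coefficients
  expect_equal(mec$mean, b[1] + b[2] * mec$day + b[3] * mec$day^2,
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_true(all(mec$lower <= mec$mean & mec$mean <= mec$upper))
  # positive-valence affect decreases in magnitude across the window
  expect_lt(mec$mean[mec$day == 63], mec$mean[mec$day == 4])
  expect_warning(marginal_effect_curve(fit, t_grid = 60:70), "extrapolation")
})

test_that("unobserved-participant predictions widen with the RE spread", {
  fit <- small_fit_pos()
  pu <- predict_unobserved_participants(fit, n_new = 300, seed = 5)
  mec <- marginal_effect_curve(fit)
  # new-participant uncertainty strictly exceeds fixed-effect uncertainty
  expect_true(mean((pu$summary$upper - pu$summary$lower) -
                     (mec$upper - mec$lower)) > 0)
  # same discounting shape as the marginal curve
  expect_lt(pu$summary$mean[60], pu$summary$mean[1])
  expect_equal(dim(pu$draws), c(300, 60))
})

test_that("posterior predictive checks separate fit from misfit", {
  fit <- small_fit_pos()
  ppc <- posterior_predictive_check(fit, n_reps = 50, seed = 2)
  expect_true(ppc$good_fit)
  expect_true(all(c("affect", "observed", "replicated") %in%
                    names(ppc$density_export)))
  # inject a strong cubic distortion: the observed data leave the
  # replicate-to-replicate distance cloud
  fit2 <- fit
  fit2$data$y <- fit2$data$y + 0.0008 * fit2$data$t^3
  ppc2 <- posterior_predictive_check(fit2, n_reps = 50, seed = 2)
  expect_gt(median(ppc2$ks_obs), max(ppc2$ks_rep))
})

test_that("posterior means are insensitive to doubling the prior scales", {
  cfg <- cohort_config(n_participants = 60, seed = 77)
  sim <- suppressMessages(simulate_cohort(cfg))
  mc1 <- mcmc_config(n_chains = 2, n_iterations = 900, n_warmup = 400,
                     n_adapt = 300, seed = 21)
  mc2 <- mcmc_config(n_chains = 2, n_iterations = 900, n_warmup = 400,
                     n_adapt = 300, seed = 21, prior_scale = 2)
  f1 <- suppressWarnings(fit_discount_model(sim$panel, "positive", mc1))
  f2 <- suppressWarnings(fit_discount_model(sim$panel, "positive", mc2))
  b1 <- colMeans(f1$B); b2 <- colMeans(f2$B)
  psd <- apply(f1$B, 2, sd)
  expect_lt(abs(b2[1] - b1[1]) / abs(b1[1]), 0.05)
  # slope shifts stay within Monte-Carlo noise of the posterior
  expect_true(all(abs(b2[-1] - b1[-1]) < 0.5 * psd[-1]))
})

test_that("fits are reproducible given the seed", {
  mc <- small_mcmc(301)
  f1 <- suppressWarnings(fit_discount_model(small_cohort()$panel, "positive", mc))
  expect_equal(colMeans(f1$B), colMeans(small_fit_pos()$B))
})

test_that("generating effects fall inside the 95% HPDI across repeated cohorts", {
  hits <- matrix(0L, nrow = 20, ncol = 3)
  mc <- mcmc_config(n_chains = 2, n_iterations = 1000, n_warmup = 300,
                    n_adapt = 300, seed = 55)
  for (s in 1:20) {
    cfg <- cohort_config(n_participants = 60, seed = 70000 + s)
    sim <- suppressMessages(simulate_cohort(cfg))
    fit <- suppressWarnings(fit_discount_model(sim$panel, "positive", mc))
    sm <- fit$summary[fit$summary$parameter %in% c("Intercept", "Time", "Time^2"), ]
    sm <- sm[match(c("Intercept", "Time", "Time^2"), sm$parameter), ]
    hits[s, ] <- as.integer(sm$hpdi_low <= table1_pos & table1_pos <= sm$hpdi_high)
  }
  # each fixed effect covered in at least 85% of cohorts
  expect_true(all(colMeans(hits) >= 0.85))
})
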