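test_that("event schedule arithmetic follows the follow-up design", {
  cfg <- cohort_config(n_participants = 5, seed = 3)
  sched <- build_event_schedule(cfg)
  # an event on the baseline day is rated at 4, 8, ..., 32 days
  ev0 <- sched$encoding$event_id[sched$encoding$event_day == 0]
  if (length(ev0)) {
    d <- sched$schedule$time_distance_days[sched$schedule$event_id == ev0[1]]
    expect_equal(d, seq(4, 32, by = 4))
  }
  # the oldest allowed event reaches the 63-day maximum at the last wave
  cfg2 <- cohort_config(n_participants = 200, seed = 4)
  sch2 <- build_event_schedule(cfg2)
  expect_true(any(sch2$encoding$event_day == -31))
  expect_equal(max(sch2$schedule$time_distance_days), 63)
  expect_true(all(sch2$schedule$time_distance_days >= 4 &
                    sch2$schedule$time_distance_days <= 63))
  # distances increase by the wave interval within each event
  one <- sch2$schedule[sch2$schedule$event_id == sch2$schedule$event_id[1], ]
  expect_equal(diff(one$time_distance_days), rep(4, 7))
  expect_true(all(sch2$encoding$encoding_intensity >= 35 &
                    sch2$encoding$encoding_intensity <= 100))
})

test_that("configuration errors are caught by name", {
  expect_error(cohort_config(n_participants = 0), "n_participants")
  expect_error(cohort_config(n_waves = -1), "n_waves")
  bad_corr <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3, 3)
  expect_error(cohort_config(re_corr_participant = bad_corr),
               "re_corr_participant")
  expect_error(cohort_config(re_sd_participant = c(-1, 0, 0)),
               "standard deviations")
  expect_error(cohort_config(cross_valence_corr = 1.5), "cross_valence_corr")
})

test_that("true paths equal the fixed effects when all random SDs are zero", {
  cfg <- noiseless_config(n = 4)
  truth <- sample_true_paths(cfg)
  pos <- truth$participant_paths[truth$participant_paths$valence == 1, ]
  neg <- truth$participant_paths[truth$participant_paths$valence == -1, ]
  expect_equal(unname(as.matrix(pos[c("b0", "b1", "b2")])),
               matrix(table1_pos, 4, 3, byrow = TRUE))
  expect_equal(unname(as.matrix(neg[c("b0", "b1", "b2")])),
               matrix(table1_neg, 4, 3, byrow = TRUE))
  expect_true(all(truth$event_intercepts$e0 == 0))
})

test_that("participant deviations recover the configured covariance", {
  sds <- c(8, 0.2, 0.003)
  corr <- matrix(c(1, 0.3, 0, 0.3, 1, -0.2, 0, -0.2, 1), 3, 3)
  cfg <- cohort_config(n_participants = 4000, re_sd_participant = sds,
                       re_corr_participant = corr, cross_valence_corr = 0.5,
                       seed = 12)
  truth <- sample_true_paths(cfg)
  pos <- truth$participant_paths[truth$participant_paths$valence == 1, ]
  dev <- cbind(pos$b0 - table1_pos[1], pos$b1 - table1_pos[2],
               pos$b2 - table1_pos[3])
  emp <- cov(dev)
  target <- diag(sds) %*% corr %*% diag(sds)
  # moment recovery: each covariance entry within ~4 standard errors
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((target[i, i] * target[j, j] + target[i, j]^2) / 4000)
    expect_lt(abs(emp[i, j] - target[i, j]), 4 * se)
  }
  neg <- truth$participant_paths[truth$participant_paths$valence == -1, ]
  # the coupling acts in the affect-magnitude direction: stronger positive
  # intercepts go with stronger (more negative) negative intercepts
  r <- cor(pos$b0 - table1_pos[1], -(neg$b0 - table1_neg[1]))
  expect_lt(abs(r - 0.5), 0.05)
})

test_that("affect panel respects bounds, schedule and noise model", {
  cfg <- cohort_config(n_participants = 210, seed = 21)
  sim <- suppressMessages(simulate_cohort(cfg))
  expect_equal(nrow(sim$panel), 210 * 6 * 8)
  expect_true(all(sim$panel$affect_rating >= -100 & sim$panel$affect_rating <= 100))
  # clipping is rare at default parameters
  expect_lt(sim$n_clipped / nrow(sim$panel), 0.01)
  # every event has exactly n_waves observations
  expect_true(all(table(sim$panel$event_id) == 8))
  # noiseless cohort reproduces the fixed-effect polynomial exactly
  nl <- suppressMessages(simulate_cohort(noiseless_config(n = 3)))
  pos <- nl$panel[nl$panel$valence == 1, ]
  expected <- table1_pos[1] + table1_pos[2] * pos$time_distance_days +
    table1_pos[3] * pos$time_distance_days^2
  expect_equal(pos$affect_rating, expected)
})

test_that("empirical mean path tracks the fixed-effect polynomial", {
  cfg <- cohort_config(n_participants = 2000, seed = 31)
  sim <- suppressMessages(simulate_cohort(cfg))
  pos <- sim$panel[sim$panel$valence == 1, ]
  for (day in c(8, 24, 48)) {
    rows <- pos[pos$time_distance_days == day, ]
    expected <- table1_pos[1] + table1_pos[2] * day + table1_pos[3] * day^2
    se <- sd(rows$affect_rating) / sqrt(nrow(rows))
    expect_lt(abs(mean(rows$affect_rating) - expected), 3 * se)
  }
})

test_that("scale scores carry the configured link to true discounting rates", {
  # null link: no correlation with the true AUCs
  se0 <- default_scale_effects()
  se0$gamma_pos <- 0; se0$gamma_neg <- 0
  cfg0 <- cohort_config(n_participants = 600, scale_effects = se0, seed = 41)
  sim0 <- suppressMessages(simulate_cohort(cfg0))
  r <- cor(sim0$scales$wemwbs, sim0$truth$true_auc$auc_pos_true)
  expect_lt(abs(r), 0.1)
  # deterministic link with unit effect: regression recovers beta ~ (1, 0)
  se1 <- default_scale_effects()[1, ]
  se1$gamma_pos <- 1; se1$gamma_neg <- 0; se1$resid_sd <- 0
  cfg1 <- cohort_config(n_participants = 500, scale_effects = se1, seed = 42)
  sim1 <- suppressMessages(simulate_cohort(cfg1))
  reg <- standardized_regression(
    sim1$scales$wemwbs,
    data.frame(auc_pos = sim1$truth$true_auc$auc_pos_true,
               auc_neg = sim1$truth$true_auc$auc_neg_true))
  expect_lt(abs(reg$estimate[reg$term == "auc_pos"] - 1), 0.03)
  expect_lt(abs(reg$estimate[reg$term == "auc_neg"]), 0.03)
  # totals stay inside the instrument ranges
  se <- default_scale_effects()
  cfg <- cohort_config(n_participants = 300, seed = 43)
  sim <- suppressMessages(simulate_cohort(cfg))
  for (k in seq_len(nrow(se))) {
    v <- sim$scales[[se$scale[k]]]
    expect_true(all(v >= se$min[k] & v <= se$max[k]))
  }
  # impossible latent R^2 errors
  se_bad <- default_scale_effects()
  se_bad$gamma_pos <- 1.2; se_bad$gamma_neg <- 1.2
  cfg_bad <- cohort_config(n_participants = 100, scale_effects = se_bad, seed = 44)
  expect_error(suppressMessages(simulate_cohort(cfg_bad)), "latent R\\^2")
})

test_that("simulation is deterministic given the config seed", {
  cfg <- cohort_config(n_participants = 15, seed = 99)
  a <- suppressMessages(simulate_cohort(cfg))
  b <- suppressMessages(simulate_cohort(cfg))
  expect_identical(a$panel, b$panel)
  expect_identical(a$scales, b$scales)
  expect_identical(a$truth$participant_paths, b$truth$participant_paths)
  # and a single-participant cohort is valid
  one <- suppressMessages(simulate_cohort(cohort_config(n_participants = 1, seed = 5)))
  expect_equal(nrow(one$panel), 48)
  expect_equal(length(unique(one$panel$participant_id)), 1L)
})
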