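#' Configure a synthetic affect-recall cohort
#'
#' Defines the generative model for a longitudinal affect-recall study:
#' each participant recalls `n_events_per_valence` positive and negative
#' events from the past `max_event_age_days` days and rates the affect
#' elicited by recalling each event at `n_waves` follow-ups spaced
#' `wave_interval_days` apart (first follow-up one interval after baseline).
#' Ratings follow a quadratic trajectory in time distance (days since the
#' event) with participant-level random intercept/linear/quadratic
#' deviations, an event-within-participant random intercept, and Gaussian
#' residual noise, clipped to the -100..100 visual-analog range.
#'
#' Defaults reproduce the reference study design: 210 participants, 3 events
#' per valence, 8 waves every 4 days, events up to 31 days old at baseline,
#' so time distances span 4-63 days. Default fixed effects are the published
#' population-level estimates for the two valences; random-effect and
#' residual spreads are plausible values (the source analysis does not print
#' them) and are documented as unvalidated.
#'
#' @param n_participants number of participants.
#' @param n_events_per_valence events recalled per participant per valence.
#' @param n_waves number of follow-up waves.
#' @param wave_interval_days days between consecutive waves.
#' @param max_event_age_days maximum event age at baseline, days.
#' @param fixed_effects_pos,fixed_effects_neg length-3 numeric
#'   (intercept, linear, quadratic) population trajectories, affect units,
#'   units/day, units/day^2.
#' @param re_sd_participant length-3 SDs of participant deviations for
#'   intercept, linear and quadratic terms.
#' @param re_corr_participant 3x3 correlation matrix of participant
#'   deviations (within valence).
#' @param cross_valence_corr correlation between the two valences'
#'   participant intercept deviations, in \[-1, 1\].
#' @param re_sd_event SD of the event-within-participant intercept deviation.
#' @param residual_sd SD of the observation-level Gaussian residual.
#' @param scale_effects data frame of per-scale generative effects, see
#'   [default_scale_effects()].
#' @param seed master seed; all stages derive their own streams from it.
#' @return A list of class `ptd_cohort_config`.
#' @export
cohort_config <- function(n_participants = 210,
                          n_events_per_valence = 3,
                          n_waves = 8,
                          wave_interval_days = 4,
                          max_event_age_days = 31,
                          fixed_effects_pos = c(67.806, -0.816, 0.007),
                          fixed_effects_neg = c(-51.569, 0.683, -0.006),
                          re_sd_participant = c(10, 0.15, 0.002),
                          re_corr_participant = diag(3),
                          cross_valence_corr = 0.4,
                          re_sd_event = 8,
                          residual_sd = 12,
                          scale_effects = default_scale_effects(),
                          seed = 1L) {
  check_count(n_participants, "n_participants")
  check_count(n_events_per_valence, "n_events_per_valence")
  check_count(n_waves, "n_waves")
  check_count(wave_interval_days, "wave_interval_days")
  check_count(max_event_age_days, "max_event_age_days", min = 0L)
  stopifnot(length(fixed_effects_pos) == 3, length(fixed_effects_neg) == 3)
  if (any(re_sd_participant < 0) || re_sd_event < 0 || residual_sd < 0) {
    stop("all standard deviations must be >= 0")
  }
  check_psd(re_corr_participant, "re_corr_participant")
  if (abs(cross_valence_corr) > 1) stop("cross_valence_corr must be in [-1, 1]")
  check_psd(joint_re_covariance(re_sd_participant, re_corr_participant,
                                cross_valence_corr,
                                c(fixed_effects_pos[1], fixed_effects_neg[1])),
            "joint participant random-effect covariance")
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_events_per_valence = as.integer(n_events_per_valence),
    n_waves = as.integer(n_waves),
    wave_interval_days = as.integer(wave_interval_days),
    max_event_age_days = as.integer(max_event_age_days),
    fixed_effects_pos = as.numeric(fixed_effects_pos),
    fixed_effects_neg = as.numeric(fixed_effects_neg),
    re_sd_participant = as.numeric(re_sd_participant),
    re_corr_participant = unname(as.matrix(re_corr_participant)),
    cross_valence_corr = as.numeric(cross_valence_corr),
    re_sd_event = as.numeric(re_sd_event),
    residual_sd = as.numeric(residual_sd),
    scale_effects = validate_scale_effects(scale_effects),
    seed = as.integer(seed)
  )
  class(cfg) <- "ptd_cohort_config"
  cfg
}

#' Default generative effects of discounting rates on mental-health scales
#'
#' One row per questionnaire: the standardized effects (`gamma_pos`,
#' `gamma_neg`) of the true AUC-positive and AUC-negative scores on the
#' latent scale outcome, the instrument's total-score range, and the latent
#' residual SD (`NA` = auto-completed so the latent outcome has unit
#' variance, which makes a standardized two-predictor regression recover the
#' gammas directly). Default gammas follow the published effect pattern:
#' well-being rises with slow positive-event discounting, the four distress
#' scales rise with slow negative-event discounting.
#'
#' @return A tibble with columns `scale`, `gamma_pos`, `gamma_neg`,
#'   `resid_sd`, `min`, `max`.
#' @export
default_scale_effects <- function() {
  tibble::tibble(
    scale     = c("wemwbs", "bdi", "tai", "pss", "rrs"),
    gamma_pos = c(0.284, -0.131, -0.178, -0.162, -0.120),
    gamma_neg = c(-0.133, 0.139, 0.164, 0.149, 0.147),
    resid_sd  = NA_real_,
    min       = c(14, 0, 20, 0, 22),
    max       = c(70, 63, 80, 40, 88)
  )
}

validate_scale_effects <- function(se) {
  need <- c("scale", "gamma_pos", "gamma_neg", "resid_sd", "min", "max")
  missing <- setdiff(need, names(se))
  if (length(missing)) stop("scale_effects lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(se$scale)) stop("duplicate scale names in scale_effects")
  tibble::as_tibble(se[need])
}

# 6x6 covariance of (u0,u1,u2)_pos and (u0,u1,u2)_neg: within-valence blocks
# share the configured SDs/correlations; the only cross-valence coupling is
# between the two intercept deviations, in the affect-MAGNITUDE direction
# (a trait for strong affect strengthens both valences' initial intensity,
# i.e. pushes the two intercepts apart since they have opposite signs).
# This is what makes the two discounting rates correlate positively.
joint_re_covariance <- function(sds, corr, rho_cross, sign_pair = c(1, -1)) {
  block <- diag(sds) %*% corr %*% diag(sds)
  sigma <- matrix(0, 6, 6)
  sigma[1:3, 1:3] <- block
  sigma[4:6, 4:6] <- block
  s <- sign(sign_pair[1] * sign_pair[2])
  if (s == 0) s <- 1
  sigma[1, 4] <- sigma[4, 1] <- s * rho_cross * sds[1]^2
  sigma
}

#' Build the event schedule for a cohort
#'
#' Draws each event's age at baseline (uniform over the allowed window) and
#' its encoding intensity (truncated normal, at least 35 on the 0-100 scale,
#' mirroring the study's inclusion rule that recalled events must still
#' arouse detectable affect), then lays out the follow-up waves. The time
#' distance of wave w is `w * wave_interval_days - event_day`, so with the
#' default schedule distances span 4 to 63 days.
#'
#' @param config a [cohort_config()].
#' @param seed RNG seed for this stage (defaults to a stream derived from
#'   the config master seed).
#' @return list with `encoding` (participant_id, event_id, valence,
#'   event_day, encoding_intensity) and `schedule` (adds wave and
#'   time_distance_days rows, one per event-wave).
#' @export
build_event_schedule <- function(config, seed = derive_seed(config$seed, "schedule")) {
  stopifnot(inherits(config, "ptd_cohort_config"))
  set.seed(seed)
  P <- config$n_participants
  Epv <- config$n_events_per_valence
  n_events <- P * Epv * 2L
  participant_id <- rep(seq_len(P), each = Epv * 2L)
  valence <- rep(rep(c(1L, -1L), each = Epv), times = P)
  event_id <- paste0("p", sprintf("%04d", participant_id), "_",
                     ifelse(valence > 0, "pos", "neg"),
                     rep(seq_len(Epv), times = 2L * P))
  event_day <- sample.int(config$max_event_age_days + 1L, n_events,
                          replace = TRUE) - 1L
  event_day <- -event_day
  # truncated normal on [35, 100]: baseline affect intensity during the event
  intensity <- rnorm(n_events, mean = 70, sd = 15)
  while (any(bad <- intensity < 35 | intensity > 100)) {
    intensity[bad] <- rnorm(sum(bad), mean = 70, sd = 15)
  }
  encoding <- tibble::tibble(
    participant_id = participant_id,
    event_id = event_id,
    valence = valence,
    event_day = as.integer(event_day),
    encoding_intensity = round(intensity)
  )
  waves <- seq_len(config$n_waves)
  schedule <- tibble::tibble(
    participant_id = rep(participant_id, each = config$n_waves),
    event_id = rep(event_id, each = config$n_waves),
    valence = rep(valence, each = config$n_waves),
    wave = rep(waves, times = n_events),
    time_distance_days = rep(waves * config$wave_interval_days, times = n_events) -
      rep(as.integer(event_day), each = config$n_waves)
  )
  list(encoding = encoding, schedule = schedule)
}

#' Draw true trajectories for every participant and event
#'
#' Samples participant deviations (intercept, linear, quadratic) jointly for
#' both valences from the configured covariance (the two valences' intercept
#' deviations are coupled by `cross_valence_corr`), and event intercept
#' deviations nested within participants. The true per-participant path is
#' fixed effects plus that participant's deviations; true AUC scores are the
#' closed-form integral of the scaled true path (see
#' [auc_exact_quadratic()]).
#'
#' @param config a [cohort_config()].
#' @param schedule output of [build_event_schedule()]; used only for event ids.
#' @param seed RNG seed for this stage.
#' @return list of class `ptd_truth`: `participant_paths`,
#'   `event_intercepts`, `true_auc`, `scale_effects`.
#' @export
sample_true_paths <- function(config, schedule = build_event_schedule(config),
                              seed = derive_seed(config$seed, "paths")) {
  stopifnot(inherits(config, "ptd_cohort_config"))
  set.seed(seed)
  P <- config$n_participants
  sigma <- joint_re_covariance(config$re_sd_participant,
                               config$re_corr_participant,
                               config$cross_valence_corr,
                               c(config$fixed_effects_pos[1],
                                 config$fixed_effects_neg[1]))
  check_psd(sigma, "joint participant random-effect covariance")
  u <- MASS::mvrnorm(P, mu = rep(0, 6), Sigma = sigma)
  if (P == 1L) u <- matrix(u, nrow = 1)
  paths <- tibble::tibble(
    participant_id = rep(seq_len(P), times = 2L),
    valence = rep(c(1L, -1L), each = P),
    b0 = c(config$fixed_effects_pos[1] + u[, 1],
           config$fixed_effects_neg[1] + u[, 4]),
    b1 = c(config$fixed_effects_pos[2] + u[, 2],
           config$fixed_effects_neg[2] + u[, 5]),
    b2 = c(config$fixed_effects_pos[3] + u[, 3],
           config$fixed_effects_neg[3] + u[, 6])
  )
  enc <- schedule$encoding
  event_intercepts <- tibble::tibble(
    participant_id = enc$participant_id,
    event_id = enc$event_id,
    valence = enc$valence,
    e0 = rnorm(nrow(enc), 0, config$re_sd_event)
  )
  true_auc <- tibble::tibble(
    participant_id = seq_len(P),
    auc_pos_true = vapply(seq_len(P), function(i) {
      auc_exact_quadratic(unlist(paths[paths$valence == 1L, ][i, c("b0", "b1", "b2")]))
    }, numeric(1)),
    auc_neg_true = vapply(seq_len(P), function(i) {
      auc_exact_quadratic(unlist(paths[paths$valence == -1L, ][i, c("b0", "b1", "b2")]))
    }, numeric(1))
  )
  out <- list(participant_paths = paths,
              event_intercepts = event_intercepts,
              true_auc = true_auc,
              scale_effects = config$scale_effects)
  class(out) <- "ptd_truth"
  out
}

#' Generate the longitudinal affect panel
#'
#' Evaluates each event's true trajectory (participant path plus event
#' intercept deviation) at its scheduled time distances, adds Gaussian
#' residual noise, and clips to the -100..100 visual-analog bounds. The
#' number of clipped ratings is reported as a message and attached as the
#' `n_clipped` attribute.
#'
#' @param truth a `ptd_truth` from [sample_true_paths()].
#' @param schedule output of [build_event_schedule()].
#' @param config the [cohort_config()].
#' @param seed RNG seed for this stage.
#' @param quiet suppress the clipping message.
#' @return tibble of affect observations (participant_id, event_id, valence,
#'   wave, time_distance_days, affect_rating).
#' @export
generate_affect_panel <- function(truth, schedule, config,
                                  seed = derive_seed(config$seed, "panel"),
                                  quiet = FALSE) {
  stopifnot(inherits(truth, "ptd_truth"))
  set.seed(seed)
  sch <- schedule$schedule
  paths <- truth$participant_paths
  key <- paste(sch$participant_id, sch$valence)
  pkey <- paste(paths$participant_id, paths$valence)
  idx <- match(key, pkey)
  if (anyNA(idx)) stop("schedule and truth are inconsistent: unmatched participant/valence")
  e0 <- truth$event_intercepts$e0[match(sch$event_id, truth$event_intercepts$event_id)]
  t <- sch$time_distance_days
  mu <- paths$b0[idx] + e0 + paths$b1[idx] * t + paths$b2[idx] * t^2
  rating <- mu + rnorm(length(mu), 0, config$residual_sd)
  n_clipped <- sum(rating < -100 | rating > 100)
  rating <- pmin(100, pmax(-100, rating))
  if (!quiet) {
    message(sprintf("affect panel: %d of %d ratings clipped to [-100, 100] (%.2f%%)",
                    n_clipped, length(rating), 100 * n_clipped / length(rating)))
  }
  panel <- tibble::tibble(
    participant_id = sch$participant_id,
    event_id = sch$event_id,
    valence = sch$valence,
    wave = sch$wave,
    time_distance_days = t,
    affect_rating = rating
  )
  attr(panel, "n_clipped") <- n_clipped
  panel
}

#' Generate mental-health scale totals linked to true discounting rates
#'
#' For each questionnaire the latent outcome is
#' `gamma_pos * z(AUC_pos_true) + gamma_neg * z(AUC_neg_true) + e`, with the
#' residual SD auto-completed (when `NA`) so the latent outcome has unit
#' variance; the latent score is then mapped affinely into the instrument's
#' total-score range (midpoint centre, an eighth of the range per latent SD),
#' rounded to integer totals and clipped to the range.
#'
#' @param truth a `ptd_truth`.
#' @param config the [cohort_config()].
#' @param seed RNG seed for this stage.
#' @return tibble with participant_id and one integer column per scale.
#' @export
generate_scale_scores <- function(truth, config,
                                  seed = derive_seed(config$seed, "scales")) {
  stopifnot(inherits(truth, "ptd_truth"))
  set.seed(seed)
  se <- config$scale_effects
  zscore <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))  # degenerate cohort
    (x - mean(x)) / s
  }
  zp <- zscore(truth$true_auc$auc_pos_true)
  zn <- zscore(truth$true_auc$auc_neg_true)
  n <- length(zp)
  out <- tibble::tibble(participant_id = truth$true_auc$participant_id)
  for (k in seq_len(nrow(se))) {
    sys <- se$gamma_pos[k] * zp + se$gamma_neg[k] * zn
    var_sys <- if (n < 2L) 0 else var(sys)
    resid_sd <- se$resid_sd[k]
    if (is.na(resid_sd)) {
      if (var_sys > 1) {
        stop(sprintf("scale '%s': systematic variance %.3f exceeds 1 (latent R^2 > 1)",
                     se$scale[k], var_sys))
      }
      resid_sd <- sqrt(1 - var_sys)
    }
    latent <- sys + rnorm(n, 0, resid_sd)
    lo <- se$min[k]; hi <- se$max[k]
    raw <- (lo + hi) / 2 + latent * (hi - lo) / 8
    out[[se$scale[k]]] <- as.integer(pmin(hi, pmax(lo, round(raw))))
  }
  out
}

#' Simulate a complete cohort
#'
#' Orchestrates schedule, true paths, affect panel and scale scores, all
#' seeded from the config's master seed, so identical configs yield
#' identical cohorts.
#'
#' @param config a [cohort_config()].
#' @param quiet suppress the clipping message.
#' @return list of class `ptd_cohort`: `encoding`, `panel`, `scales`,
#'   `truth`, `n_clipped`.
#' @export
simulate_cohort <- function(config, quiet = FALSE) {
  sched <- build_event_schedule(config)
  truth <- sample_true_paths(config, sched)
  panel <- generate_affect_panel(truth, sched, config, quiet = quiet)
  scales <- generate_scale_scores(truth, config)
  out <- list(encoding = sched$encoding, panel = panel, scales = scales,
              truth = truth, n_clipped = attr(panel, "n_clipped"))
  class(out) <- "ptd_cohort"
  out
}
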