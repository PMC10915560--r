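#' Paired permutation test
#'
#' Observed statistic is the paired t on the differences `x - y`; the null
#' distribution is built by randomly sign-flipping the differences (the
#' standard permutation scheme for paired designs). The two-sided p-value
#' uses the add-one correction `(#{|t*| >= |t|} + 1) / (n_perm + 1)`, so it
#' is never exactly zero. The effect size is Cohen's d for paired designs
#' (d_z = mean difference over SD of differences = t / sqrt(n)).
#'
#' @param x,y paired numeric vectors.
#' @param n_perm number of sign-flip permutations.
#' @param seed RNG seed.
#' @return list of class `ptd_perm`: statistic, d, permutation_p,
#'   n_permutations, n, seed.
#' @export
paired_permutation_test <- function(x, y, n_perm = 1000, seed = 1L) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  ok <- complete.cases(x, y)
  d <- x[ok] - y[ok]
  n <- length(d)
  if (n < 2L) stop("need at least 2 pairs")
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      # identical pairs: no evidence of a difference
      return(structure(list(statistic = 0, d = 0, permutation_p = 1,
                            n_permutations = n_perm, n = n, seed = seed,
                            type = "paired_t"),
                       class = "ptd_perm"))
    }
    stop("zero-variance differences; the paired t statistic is undefined")
  }
  t_obs <- mean(d) / (sd(d) / sqrt(n))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n_perm * n, replace = TRUE), nrow = n_perm)
  flipped <- signs * matrix(d, nrow = n_perm, ncol = n, byrow = TRUE)
  ms <- rowMeans(flipped)
  ss <- sqrt((rowSums(flipped^2) - n * ms^2) / (n - 1))
  t_null <- ms / (ss / sqrt(n))
  p <- (sum(abs(t_null) >= abs(t_obs)) + 1) / (n_perm + 1)
  structure(list(statistic = t_obs, d = t_obs / sqrt(n), permutation_p = p,
                 n_permutations = n_perm, n = n, seed = seed,
                 type = "paired_t"),
            class = "ptd_perm")
}

#' Permutation Spearman correlation
#'
#' Spearman's rho (rank correlation with average ranks for ties); the null
#' distribution permutes `y` against `x`. Two-sided p with the add-one
#' correction.
#'
#' @param x,y numeric vectors.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list of class `ptd_perm`: statistic (rho), permutation_p,
#'   n_permutations, n, seed.
#' @export
spearman_permutation <- function(x, y, n_perm = 1000, seed = 1L) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (sd(x) == 0 || sd(y) == 0) stop("constant input; rank correlation undefined")
  rx <- rank(x); ry <- rank(y)
  rho_obs <- cor(rx, ry)
  set.seed(seed)
  rho_null <- vapply(seq_len(n_perm), function(i) cor(rx, sample(ry)), numeric(1))
  p <- (sum(abs(rho_null) >= abs(rho_obs)) + 1) / (n_perm + 1)
  structure(list(statistic = rho_obs, d = NA_real_, permutation_p = p,
                 n_permutations = n_perm, n = n, seed = seed,
                 type = "spearman"),
            class = "ptd_perm")
}

#' @export
print.ptd_perm <- function(x, ...) {
  lab <- if (x$type == "spearman") "Spearman rho" else "paired t"
  cat(sprintf("%s = %.3f, permutation p = %.4g (%d permutations, n = %d)",
              lab, x$statistic, x$permutation_p, x$n_permutations, x$n))
  if (x$type == "paired_t") cat(sprintf(", Cohen's d = %.3f", x$d))
  cat("\n")
  invisible(x)
}

#' Standardized multiple regression
#'
#' Z-scores the outcome and every predictor over complete cases, then fits
#' ordinary least squares; the coefficients are standardized betas with 95%
#' confidence intervals and two-sided p-values.
#'
#' @param outcome numeric outcome vector.
#' @param predictors data frame (or named list) of numeric predictors.
#' @param outcome_name label used in the report.
#' @return tibble with outcome, term, estimate, ci_low, ci_high, p, n.
#' @export
standardized_regression <- function(outcome, predictors,
                                    outcome_name = "outcome") {
  predictors <- as.data.frame(predictors)
  ok <- complete.cases(outcome, predictors)
  y <- outcome[ok]
  X <- predictors[ok, , drop = FALSE]
  n <- length(y)
  if (n <= ncol(X) + 1L) stop("too few complete cases for regression")
  if (ncol(X) >= 2L) {
    cc <- cor(X)
    if (any(abs(cc[upper.tri(cc)]) >= 1 - 1e-12)) {
      stop("perfectly collinear predictors")
    }
  }
  zy <- as.numeric(scale(y))
  zX <- as.data.frame(lapply(X, function(v) as.numeric(scale(v))))
  dat <- cbind(data.frame(.y = zy), zX)
  fit <- lm(.y ~ ., data = dat)
  est <- coef(fit)[-1]
  ci <- confint(fit, level = 0.95)[-1, , drop = FALSE]
  ps <- summary(fit)$coefficients[-1, 4]
  tibble::tibble(outcome = outcome_name, term = names(est),
                 estimate = unname(est),
                 ci_low = unname(ci[, 1]), ci_high = unname(ci[, 2]),
                 p = unname(ps), n = n)
}

#' Mental-health regression battery
#'
#' Joins the AUC records to the scale totals (excluded participants are
#' dropped), fits one standardized regression per questionnaire with
#' AUC-positive and AUC-negative as predictors, and correlates the PTD bias
#' with each scale by permutation Spearman correlation. No multiple-testing
#' correction is applied (per-outcome p-values are reported as-is, and the
#' output flags this).
#'
#' @param auc_records tibble from [score_cohort()].
#' @param scale_scores tibble from [generate_scale_scores()] (participant_id
#'   plus one column per scale).
#' @param scales character vector of scale columns to analyse.
#' @param n_perm permutations for the bias correlations.
#' @param seed RNG seed.
#' @return tibble with analysis, outcome, term, estimate, ci_low, ci_high,
#'   p, n; attribute `note` flags the absence of multiplicity correction.
#' @export
run_mental_health_models <- function(auc_records, scale_scores,
                                     scales = c("wemwbs", "bdi", "tai", "pss", "rrs"),
                                     n_perm = 1000, seed = 1L) {
  missing <- setdiff(scales, names(scale_scores))
  if (length(missing)) {
    stop("scale_scores is missing column(s): ", paste(missing, collapse = ", "))
  }
  inc <- auc_records[auc_records$included, ]
  dat <- merge(inc, scale_scores, by = "participant_id")
  out <- list()
  for (sc in scales) {
    reg <- standardized_regression(dat[[sc]],
                                   dat[c("auc_pos", "auc_neg")],
                                   outcome_name = sc)
    reg <- cbind(tibble::tibble(analysis = rep("regression", nrow(reg))), reg)
    out[[length(out) + 1L]] <- reg
    ct <- spearman_permutation(dat$ptd_bias, dat[[sc]], n_perm = n_perm,
                               seed = derive_seed(seed, "inference") + match(sc, scales))
    out[[length(out) + 1L]] <- tibble::tibble(
      analysis = "bias_correlation", outcome = sc, term = "ptd_bias",
      estimate = ct$statistic, ci_low = NA_real_, ci_high = NA_real_,
      p = ct$permutation_p, n = ct$n)
  }
  res <- do.call(rbind, out)
  attr(res, "note") <- "per-outcome p-values; no multiple-testing correction applied"
  res
}

#' Monte Carlo power simulation for detecting discounting paths
#'
#' Repeatedly simulates cohorts from the generative config and refits a fast
#' frequentist model, counting how often the linear time effect is
#' significant at `alpha`. The default refitter fits a per-participant OLS
#' quadratic and runs a one-sample t-test on the participant linear
#' coefficients; `refitter = "lmer"` fits the full mixed model via lme4
#' (with Satterthwaite p-values when lmerTest is available) and is slower.
#'
#' @param config a [cohort_config()]; its fixed effects and variance
#'   components define the alternative being detected.
#' @param n_participants cohort size per simulation (defaults to the
#'   config's).
#' @param n_sims number of simulations (>= 20 so the binomial CI is
#'   meaningful).
#' @param alpha significance level.
#' @param valence which valence's linear effect to test.
#' @param refitter "ols" (per-participant OLS + one-sample t) or "lmer".
#' @param seed RNG seed.
#' @return list of class `ptd_power`: power, ci (95% Clopper-Pearson),
#'   n_sims, alpha, parameter, valence, refitter.
#' @export
power_simulation <- function(config, n_participants = config$n_participants,
                             n_sims = 200, alpha = 0.05,
                             valence = "positive",
                             refitter = c("ols", "lmer"), seed = 1L) {
  refitter <- match.arg(refitter)
  if (n_sims < 20) stop("n_sims must be >= 20 for a meaningful binomial CI")
  vc <- valence_code(valence)
  hits <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    cfg <- config
    cfg$n_participants <- as.integer(n_participants)
    cfg$seed <- as.integer((seed * 104729 + s * 7) %% 2147483647)
    sim <- simulate_cohort(cfg, quiet = TRUE)
    rows <- sim$panel[sim$panel$valence == vc, ]
    p <- switch(refitter,
                ols = ols_slope_test(rows),
                lmer = lmer_slope_test(rows))
    hits[s] <- is.finite(p) && p < alpha
  }
  k <- sum(hits)
  ci <- as.numeric(binom.test(k, n_sims)$conf.int)
  structure(list(power = k / n_sims, ci = ci, n_sims = n_sims, alpha = alpha,
                 parameter = "linear time effect", valence = valence_label(vc),
                 refitter = refitter, n_participants = n_participants,
                 seed = seed),
            class = "ptd_power")
}

ols_slope_test <- function(rows) {
  pids <- unique(rows$participant_id)
  slopes <- vapply(pids, function(pid) {
    r <- rows[rows$participant_id == pid, ]
    X <- cbind(1, r$time_distance_days, r$time_distance_days^2)
    stats::lm.fit(X, r$affect_rating)$coefficients[2]
  }, numeric(1))
  if (sd(slopes) == 0) return(NA_real_)
  stats::t.test(slopes)$p.value
}

lmer_slope_test <- function(rows) {
  rows$t <- rows$time_distance_days
  rows$t2 <- rows$t^2
  f <- affect_rating ~ t + t2 + (1 + t + t2 | participant_id) + (1 | event_id)
  if (requireNamespace("lmerTest", quietly = TRUE)) {
    m <- suppressWarnings(suppressMessages(
      lmerTest::lmer(f, data = rows,
                     control = lme4::lmerControl(calc.derivs = FALSE))))
    return(summary(m)$coefficients["t", "Pr(>|t|)"])
  }
  m <- suppressWarnings(suppressMessages(
    lme4::lmer(f, data = rows,
               control = lme4::lmerControl(calc.derivs = FALSE))))
  tv <- summary(m)$coefficients["t", "t value"]
  2 * pt(-abs(tv), df = nrow(rows) - length(lme4::fixef(m)))
}

#' @export
print.ptd_power <- function(x, ...) {
  cat(sprintf("power to detect the %s-valence %s: %.1f%% (95%% CI [%.2f%%, %.2f%%])\n",
              x$valence, x$parameter, 100 * x$power,
              100 * x$ci[1], 100 * x$ci[2]))
  cat(sprintf("  %d simulations, n = %d, alpha = %.3g, refitter = %s\n",
              x$n_sims, x$n_participants, x$alpha, x$refitter))
  invisible(x)
}
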