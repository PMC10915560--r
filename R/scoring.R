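#' Extract per-participant discounting paths from a fit
#'
#' A participant's path is the posterior-mean fixed effects plus the
#' posterior means of that participant's deviations; event-level deviations
#' average out and are excluded, matching the extract-then-predict scoring
#' procedure.
#'
#' @param fit a `ptd_fit`.
#' @param participants optional subset of participant ids (error if absent
#'   from the fit).
#' @return tibble with participant_id, b0, b1, b2.
#' @export
extract_individual_paths <- function(fit, participants = NULL) {
  stopifnot(inherits(fit, "ptd_fit"))
  b <- colMeans(fit$B)[1:3]
  out <- tibble::tibble(
    participant_id = fit$participant_id,
    b0 = b[1] + fit$U_mean[, "u0"],
    b1 = b[2] + fit$U_mean[, "u1"],
    b2 = b[3] + fit$U_mean[, "u2"]
  )
  if (!is.null(participants)) {
    missing <- setdiff(participants, out$participant_id)
    if (length(missing)) {
      stop("participants absent from fit: ", paste(missing, collapse = ", "))
    }
    out <- out[match(participants, out$participant_id), ]
  }
  out
}

#' Evaluate a quadratic path on a grid of time distances
#'
#' @param path numeric length-3 `(b0, b1, b2)` or a one-row data frame with
#'   those columns.
#' @param t_grid integer days, within the observed 4-63 range.
#' @return numeric vector of predicted affect intensities.
#' @export
predict_affect_grid <- function(path, t_grid = 4:63) {
  if (length(t_grid) == 0L) stop("empty time grid")
  if (any(t_grid < 4 | t_grid > 63)) {
    warning("grid extends outside the observed 4-63 day range")
  }
  if (is.data.frame(path)) path <- unlist(path[1, c("b0", "b1", "b2")])
  stopifnot(length(path) == 3)
  path[1] + path[2] * t_grid + path[3] * t_grid^2
}

#' Scale a predicted-affect curve to the unit square
#'
#' Time distances are mapped to \[0, 1\] by subtracting the first day (4)
#' and dividing by the span (59); affect is divided by its first predicted
#' value, so the curve starts at exactly 1. Dividing by a negative first
#' value (negative events) naturally yields a positive scaled curve; no
#' absolute values are taken anywhere.
#'
#' @param values predicted affect on `t_grid`.
#' @param t_grid the grid the values were predicted on.
#' @return list of class `ptd_curve` with `scaled_time`, `scaled_affect`.
#' @export
scale_discount_curve <- function(values, t_grid = 4:63) {
  if (length(values) != length(t_grid)) stop("values and t_grid lengths differ")
  if (length(values) < 2L) stop("need at least 2 grid points")
  if (values[1] == 0) stop("first predicted affect is 0; curve cannot be scaled")
  x <- (t_grid - t_grid[1]) / (t_grid[length(t_grid)] - t_grid[1])
  y <- values / values[1]
  structure(list(scaled_time = x, scaled_affect = y), class = "ptd_curve")
}

#' Trapezoid area under a scaled discounting curve
#'
#' Composite trapezoid rule over the scaled grid. The result can be negative
#' when the curve crosses zero and the sign-flipped tail dominates, which
#' violates the definition of a discounting rate and triggers exclusion in
#' [score_cohort()].
#'
#' @param curve a `ptd_curve` from [scale_discount_curve()].
#' @return scalar AUC (1 = no discounting).
#' @export
auc_trapezoid <- function(curve) {
  x <- curve$scaled_time
  y <- curve$scaled_affect
  if (length(x) < 2L) stop("need at least 2 points for the trapezoid rule")
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Exact AUC of a quadratic path (closed-form oracle)
#'
#' The scaled-curve AUC of a quadratic path has the closed form
#' `(F(63) - F(4)) / (59 * v(4))` with `F` the antiderivative of
#' `v(t) = b0 + b1 t + b2 t^2`. Serves as the analytic oracle for the
#' trapezoid rule and as a fast scoring path.
#'
#' @param path numeric `(b0, b1, b2)`.
#' @param t_min,t_max integration limits in days.
#' @return scalar AUC.
#' @export
auc_exact_quadratic <- function(path, t_min = 4, t_max = 63) {
  if (is.data.frame(path)) path <- unlist(path[1, c("b0", "b1", "b2")])
  v0 <- path[1] + path[2] * t_min + path[3] * t_min^2
  if (v0 == 0) stop("predicted affect at the first day is 0; AUC undefined")
  antider <- function(t) path[1] * t + path[2] * t^2 / 2 + path[3] * t^3 / 3
  unname((antider(t_max) - antider(t_min)) / ((t_max - t_min) * v0))
}

#' Scoring configuration
#'
#' @param t_grid prediction grid (integer days).
#' @param normalization normalization used for the PTD-bias statistic:
#'   z-score (default) or min-max over included participants.
#' @param abnormal_screen apply the abnormal-pattern screen: flag
#'   participants whose mean rating sign contradicts the event valence in at
#'   least half of the waves. This is a configurable stand-in for the
#'   original study's (unavailable) supplementary criterion; off by default.
#' @param per_draw score each posterior draw's path and average the AUCs,
#'   instead of scoring the posterior-mean path (default).
#' @return list of class `ptd_screen_config`.
#' @export
screen_config <- function(t_grid = 4:63,
                          normalization = c("zscore", "minmax"),
                          abnormal_screen = FALSE,
                          per_draw = FALSE) {
  structure(list(t_grid = t_grid,
                 normalization = match.arg(normalization),
                 abnormal_screen = abnormal_screen,
                 per_draw = per_draw),
            class = "ptd_screen_config")
}

participant_auc <- function(fit, screen) {
  paths <- extract_individual_paths(fit)
  if (!screen$per_draw) {
    auc <- vapply(seq_len(nrow(paths)), function(i) {
      v <- predict_affect_grid(unlist(paths[i, c("b0", "b1", "b2")]), screen$t_grid)
      auc_trapezoid(scale_discount_curve(v, screen$t_grid))
    }, numeric(1))
  } else {
    B <- fit$B
    auc <- vapply(seq_len(nrow(paths)), function(i) {
      b0 <- B[, 1] + fit$U_draws$u0[, i]
      b1 <- B[, 2] + fit$U_draws$u1[, i]
      b2 <- B[, 3] + fit$U_draws$u2[, i]
      mean(vapply(seq_along(b0), function(d) {
        v <- b0[d] + b1[d] * screen$t_grid + b2[d] * screen$t_grid^2
        if (v[1] == 0) return(NA_real_)
        auc_trapezoid(scale_discount_curve(v, screen$t_grid))
      }, numeric(1)), na.rm = TRUE)
    }, numeric(1))
  }
  tibble::tibble(participant_id = paths$participant_id, auc = auc)
}

abnormal_pattern_flags <- function(panel, participants) {
  # mean rating per participant x valence x wave; a participant is flagged
  # if, for either valence, the mean rating's sign contradicts the event
  # valence in at least half of the waves
  agg <- aggregate(affect_rating ~ participant_id + valence + wave,
                   data = panel, FUN = mean)
  flagged <- vapply(participants, function(pid) {
    rows <- agg[agg$participant_id == pid, ]
    any(vapply(c(1L, -1L), function(vc) {
      vr <- rows[rows$valence == vc, ]
      if (nrow(vr) == 0L) return(FALSE)
      mean(sign(vr$affect_rating) == -vc) >= 0.5
    }, logical(1)))
  }, logical(1))
  flagged
}

#' Score a cohort's discounting rates
#'
#' Computes AUC-positive and AUC-negative for every participant from the two
#' valences' fits, applies the exclusion rules (negative AUC violates the
#' definition of a discounting rate; optional abnormal-pattern screen), and
#' adds the PTD-bias statistic for included participants.
#'
#' @param fit_pos,fit_neg `ptd_fit` objects for the two valences, covering
#'   the same participants.
#' @param screen a [screen_config()].
#' @param panel affect panel, required when the abnormal-pattern screen is
#'   enabled.
#' @param quiet suppress the exclusion-count message.
#' @return tibble with participant_id, auc_pos, auc_neg, included,
#'   exclusion_reason, ptd_bias.
#' @export
score_cohort <- function(fit_pos, fit_neg, screen = screen_config(),
                         panel = NULL, quiet = FALSE) {
  if (!setequal(fit_pos$participant_id, fit_neg$participant_id)) {
    stop("the two fits cover different participant sets")
  }
  ap <- participant_auc(fit_pos, screen)
  an <- participant_auc(fit_neg, screen)
  an <- an[match(ap$participant_id, an$participant_id), ]
  rec <- tibble::tibble(
    participant_id = ap$participant_id,
    auc_pos = ap$auc, auc_neg = an$auc,
    included = TRUE, exclusion_reason = "none", ptd_bias = NA_real_
  )
  neg <- rec$auc_pos < 0 | rec$auc_neg < 0
  rec$included[neg] <- FALSE
  rec$exclusion_reason[neg] <- "negative_auc"
  if (isTRUE(screen$abnormal_screen)) {
    if (is.null(panel)) stop("abnormal-pattern screen requires the affect panel")
    flags <- abnormal_pattern_flags(panel, rec$participant_id)
    hit <- flags & rec$included
    rec$included[hit] <- FALSE
    rec$exclusion_reason[hit] <- "abnormal_pattern"
  }
  rec <- ptd_bias(rec, normalization = screen$normalization)
  if (!quiet) {
    message(sprintf("scored %d participants; excluded %d (negative AUC: %d, abnormal pattern: %d)",
                    nrow(rec), sum(!rec$included),
                    sum(rec$exclusion_reason == "negative_auc"),
                    sum(rec$exclusion_reason == "abnormal_pattern")))
  }
  rec
}

#' PTD bias: normalized AUC-positive minus normalized AUC-negative
#'
#' Positive bias means negative events discount faster than positive events
#' for that participant relative to the cohort (the fading-affect-bias
#' direction). Normalization (z-score by default, min-max optional) is
#' computed over included participants only; excluded participants get `NA`.
#'
#' @param records AUC record tibble from [score_cohort()] (or any tibble
#'   with auc_pos, auc_neg, included).
#' @param normalization "zscore" or "minmax".
#' @return `records` with the `ptd_bias` column (re)computed.
#' @export
ptd_bias <- function(records, normalization = c("zscore", "minmax")) {
  normalization <- match.arg(normalization)
  inc <- records$included
  if (sum(inc) < 2L) stop("need at least 2 included participants")
  norm <- function(x) {
    if (normalization == "zscore") {
      if (sd(x) == 0) stop("zero variance in AUC scores; bias undefined")
      (x - mean(x)) / sd(x)
    } else {
      if (max(x) == min(x)) stop("zero range in AUC scores; bias undefined")
      (x - min(x)) / (max(x) - min(x))
    }
  }
  records$ptd_bias <- NA_real_
  records$ptd_bias[inc] <- norm(records$auc_pos[inc]) - norm(records$auc_neg[inc])
  records
}
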