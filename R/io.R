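#' Write cohort tables to a directory
#'
#' Tab-separated `affect_panel.tsv`, `encoding.tsv`, `scales.tsv`, plus a
#' JSON sidecar `truth.json` with the generating paths and true AUC scores.
#'
#' @param cohort a `ptd_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort_tables <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ptd_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(panel = file.path(dir, "affect_panel.tsv"),
             encoding = file.path(dir, "encoding.tsv"),
             scales = file.path(dir, "scales.tsv"),
             truth = file.path(dir, "truth.json"))
  utils::write.table(cohort$panel, paths["panel"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$encoding, paths["encoding"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(cohort$scales, paths["scales"], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(participant_paths = cohort$truth$participant_paths,
         event_intercepts = cohort$truth$event_intercepts,
         true_auc = cohort$truth$true_auc,
         n_clipped = cohort$n_clipped),
    paths["truth"], digits = NA, auto_unbox = TRUE)
  invisible(paths)
}

#' Read and validate an affect panel
#'
#' Reads a tab-separated long-format panel and enforces the observation
#' schema: required columns present, numeric ratings within \[-100, 100\],
#' valence coded +1/-1, and no duplicated (participant, event, wave) keys.
#' Offending rows are reported with their file line numbers.
#'
#' @param path file path.
#' @return validated tibble of affect observations.
#' @export
read_affect_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("participant_id", "event_id", "valence", "wave",
            "time_distance_days", "affect_rating")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    stop("affect panel is missing column(s): ", paste(missing, collapse = ", "))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1
  bad_num <- !is.finite(suppressWarnings(as.numeric(raw$affect_rating)))
  if (any(bad_num)) {
    stop("non-numeric affect_rating at line(s): ",
         paste(head(line_no[bad_num], 10), collapse = ", "))
  }
  raw$affect_rating <- as.numeric(raw$affect_rating)
  oob <- raw$affect_rating < -100 | raw$affect_rating > 100
  if (any(oob)) {
    stop("affect_rating outside [-100, 100] at line(s): ",
         paste(head(line_no[oob], 10), collapse = ", "))
  }
  if (!all(raw$valence %in% c(1, -1))) {
    bad <- !(raw$valence %in% c(1, -1))
    stop("valence must be +1 or -1; offending line(s): ",
         paste(head(line_no[bad], 10), collapse = ", "))
  }
  key <- paste(raw$participant_id, raw$event_id, raw$wave)
  dup <- duplicated(key)
  if (any(dup)) {
    stop("duplicate (participant, event, wave) rows at line(s): ",
         paste(head(line_no[dup], 10), collapse = ", "))
  }
  tibble::as_tibble(raw)
}

#' Assemble a pipeline configuration
#'
#' Bundles the per-stage configurations; round-trips through YAML via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param cohort a [cohort_config()].
#' @param mcmc an [mcmc_config()].
#' @param screen a [screen_config()].
#' @param n_perm permutations for the inference battery.
#' @param alpha significance level.
#' @param seed master seed for the inference stage.
#' @param output_dir where [run_ptd_pipeline()] writes its artifacts.
#' @param panel_path optional path to a real affect panel; when set, the
#'   simulation stage is skipped and the panel is read from disk (scale
#'   scores must then be supplied to the inference stage separately).
#' @return list of class `ptd_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), mcmc = mcmc_config(),
                            screen = screen_config(), n_perm = 1000,
                            alpha = 0.05, seed = 1L, output_dir = "ptd_results",
                            panel_path = NULL) {
  structure(list(cohort = cohort, mcmc = mcmc, screen = screen,
                 n_perm = n_perm, alpha = alpha, seed = as.integer(seed),
                 output_dir = output_dir, panel_path = panel_path),
            class = "ptd_pipeline_config")
}

#' @rdname pipeline_config
#' @param config a `ptd_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "ptd_pipeline_config"))
  plain <- rapply(unclass(config), identity, how = "list")
  plain$cohort$re_corr_participant <- as.list(as.data.frame(config$cohort$re_corr_participant))
  plain$cohort$scale_effects <- as.list(config$cohort$scale_effects)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  ch <- raw$cohort
  cohort <- cohort_config(
    n_participants = ch$n_participants,
    n_events_per_valence = ch$n_events_per_valence,
    n_waves = ch$n_waves,
    wave_interval_days = ch$wave_interval_days,
    max_event_age_days = ch$max_event_age_days,
    fixed_effects_pos = unlist(ch$fixed_effects_pos),
    fixed_effects_neg = unlist(ch$fixed_effects_neg),
    re_sd_participant = unlist(ch$re_sd_participant),
    re_corr_participant = as.matrix(as.data.frame(ch$re_corr_participant)),
    cross_valence_corr = ch$cross_valence_corr,
    re_sd_event = ch$re_sd_event,
    residual_sd = ch$residual_sd,
    scale_effects = tibble::as_tibble(lapply(ch$scale_effects, unlist)),
    seed = ch$seed
  )
  mc <- raw$mcmc
  mcmc <- mcmc_config(n_chains = mc$n_chains, n_iterations = mc$n_iterations,
                      n_warmup = mc$n_warmup, n_adapt = mc$n_adapt,
                      seed = mc$seed, degree = mc$degree,
                      prior_scale = if (is.null(mc$prior_scale)) 1 else mc$prior_scale)
  sc <- raw$screen
  screen <- screen_config(t_grid = unlist(sc$t_grid),
                          normalization = sc$normalization,
                          abnormal_screen = sc$abnormal_screen,
                          per_draw = sc$per_draw)
  pipeline_config(cohort = cohort, mcmc = mcmc, screen = screen,
                  n_perm = raw$n_perm, alpha = raw$alpha, seed = raw$seed,
                  output_dir = raw$output_dir, panel_path = raw$panel_path)
}

#' Run the full discounting pipeline
#'
#' Simulate (or load) the affect panel, fit both valences' models, score the
#' cohort, run the inferential battery, and write all artifacts to the
#' configured output directory: cohort tables, a population-parameter
#' summary table, convergence diagnostics, the AUC table, the tidy results
#' table, and a JSON summary.
#'
#' @param config a [pipeline_config()].
#' @param scale_scores optional scale-score tibble (required when loading a
#'   panel from disk instead of simulating).
#' @param quiet suppress progress messages.
#' @return invisibly, a results bundle: cohort (or panel), fits, records,
#'   results table, and written paths.
#' @export
run_ptd_pipeline <- function(config, scale_scores = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "ptd_pipeline_config"))
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config$panel_path)) {
    say("stage simulate: generating cohort")
    cohort <- stage("simulate", simulate_cohort(config$cohort, quiet = quiet))
    panel <- cohort$panel
    scales <- cohort$scales
    stage("simulate", write_cohort_tables(cohort, config$output_dir))
  } else {
    say("stage load: reading affect panel from ", config$panel_path)
    cohort <- NULL
    panel <- stage("load", read_affect_panel(config$panel_path))
    scales <- scale_scores
  }
  say("stage fit: positive valence")
  mc_pos <- config$mcmc
  mc_pos$seed <- derive_seed(config$seed, "fit_pos")
  fit_pos <- stage("fit_positive", fit_discount_model(panel, "positive", mc_pos))
  say("stage fit: negative valence")
  mc_neg <- config$mcmc
  mc_neg$seed <- derive_seed(config$seed, "fit_neg")
  fit_neg <- stage("fit_negative", fit_discount_model(panel, "negative", mc_neg))
  summary_tab <- rbind(fit_pos$summary, fit_neg$summary)
  utils::write.table(summary_tab, file.path(config$output_dir, "model_summary.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("stage score: AUC discounting rates")
  records <- stage("score", score_cohort(fit_pos, fit_neg, config$screen,
                                         panel = panel, quiet = quiet))
  utils::write.table(records, file.path(config$output_dir, "auc_records.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  say("stage infer: permutation tests and regressions")
  inc <- records[records$included, ]
  iseed <- derive_seed(config$seed, "inference")
  paired <- stage("infer", paired_permutation_test(inc$auc_pos, inc$auc_neg,
                                                   n_perm = config$n_perm,
                                                   seed = iseed))
  rho <- stage("infer", spearman_permutation(inc$auc_pos, inc$auc_neg,
                                             n_perm = config$n_perm,
                                             seed = iseed + 1L))
  results <- tibble::tibble(
    analysis = c("paired_permutation", "spearman_permutation"),
    outcome = c("auc_pos_vs_auc_neg", "auc_pos_vs_auc_neg"),
    term = c("t", "rho"),
    estimate = c(paired$statistic, rho$statistic),
    ci_low = NA_real_, ci_high = NA_real_,
    p = c(paired$permutation_p, rho$permutation_p),
    n = c(paired$n, rho$n))
  if (!is.null(scales)) {
    mh <- stage("infer", run_mental_health_models(records, scales,
                                                  n_perm = config$n_perm,
                                                  seed = config$seed))
    results <- rbind(results, mh)
  }
  utils::write.table(results, file.path(config$output_dir, "results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(mean_auc_pos = mean(inc$auc_pos), sd_auc_pos = sd(inc$auc_pos),
         mean_auc_neg = mean(inc$auc_neg), sd_auc_neg = sd(inc$auc_neg),
         paired_t = paired$statistic, paired_d = paired$d,
         paired_p = paired$permutation_p,
         spearman_rho = rho$statistic, spearman_p = rho$permutation_p,
         n_included = nrow(inc), n_excluded = sum(!records$included),
         note = "per-outcome p-values; no multiple-testing correction applied"),
    file.path(config$output_dir, "summary.json"), digits = NA, auto_unbox = TRUE)
  say("pipeline complete: artifacts in ", config$output_dir)
  invisible(list(cohort = cohort, panel = panel, fit_pos = fit_pos,
                 fit_neg = fit_neg, records = records, results = results,
                 output_dir = config$output_dir))
}
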