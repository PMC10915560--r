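# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, force(expr), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# small cohort + both fits at reduced draws, reused across model/scoring tests
small_cohort <- function() {
  memo("small_cohort", {
    cfg <- cohort_config(n_participants = 40, seed = 101)
    suppressMessages(simulate_cohort(cfg))
  })
}

small_mcmc <- function(seed = 301) {
  mcmc_config(n_chains = 2, n_iterations = 900, n_warmup = 400,
              n_adapt = 300, seed = seed)
}

small_fit_pos <- function() {
  memo("small_fit_pos", suppressWarnings(
    fit_discount_model(small_cohort()$panel, "positive", small_mcmc(301))))
}

small_fit_neg <- function() {
  memo("small_fit_neg", suppressWarnings(
    fit_discount_model(small_cohort()$panel, "negative", small_mcmc(302))))
}

# a cohort with all random effects and residual noise switched off
noiseless_config <- function(n = 6, seed = 11) {
  cohort_config(n_participants = n, re_sd_participant = c(0, 0, 0),
                re_sd_event = 0, residual_sd = 0, cross_valence_corr = 0,
                seed = seed)
}

table1_pos <- c(67.806, -0.816, 0.007)
table1_neg <- c(-51.569, 0.683, -0.006)

# brute-force shortest-interval oracle for the HPDI
hpdi_bruteforce <- function(draws, prob = 0.95) {
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(x[1], x[n]))
  best <- c(x[1], x[m])
  for (i in seq_len(n - m + 1)) {
    if (x[i + m - 1] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + m - 1])
  }
  best
}
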