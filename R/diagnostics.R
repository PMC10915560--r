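#' Highest posterior density interval
#'
#' The shortest contiguous interval containing at least `prob` of the sorted
#' draws: all windows of `ceiling(prob * n)` consecutive order statistics are
#' scanned and the narrowest returned. Appropriate for unimodal posteriors.
#'
#' @param draws numeric vector of posterior draws.
#' @param prob interval mass, in (0, 1].
#' @return named numeric vector `c(lower, upper)`.
#' @export
hpdi <- function(draws, prob = 0.95) {
  draws <- draws[is.finite(draws)]
  if (length(draws) == 0L) stop("hpdi: no draws")
  if (!is.numeric(prob) || prob <= 0 || prob > 1) stop("hpdi: prob must be in (0, 1]")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(prob * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m):n] - x[seq_len(n - m + 1L)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m - 1L])
}

# Rank-normalize pooled draws: average ranks mapped through the normal
# quantile function with the usual (r - 3/8) / (S + 1/4) offset.
rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

split_chains <- function(chains) {
  # chains: iterations x chains matrix -> halved chains side by side
  n <- nrow(chains)
  half <- floor(n / 2)
  cbind(chains[seq_len(half), , drop = FALSE],
        chains[(n - half + 1):n, , drop = FALSE])
}

#' Rank-normalized split R-hat
#'
#' Chains are split in half, pooled draws are rank-normalized, and the
#' classical between/within-chain potential scale reduction factor is
#' computed on the normalized split chains. Values near 1 indicate that all
#' chains explore the same distribution; values above ~1.01 warrant more
#' iterations and above ~1.05 indicate failure.
#'
#' @param chains matrix of draws, iterations x chains (>= 2 chains).
#' @return scalar R-hat.
#' @export
rhat <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("rhat requires at least 2 chains")
  z <- split_chains(chains)
  z[] <- rank_normalize(as.vector(z))
  n <- nrow(z)
  if (n < 2L) stop("rhat requires at least 4 iterations per chain")
  m <- ncol(z)
  means <- colMeans(z)
  vars <- apply(z, 2, var)
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(NA_real_)
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Bulk effective sample size
#'
#' Effective sample size of the rank-normalized split chains, using
#' per-chain autocorrelations combined across chains and truncated by
#' Geyer's initial monotone positive sequence.
#'
#' @param chains matrix of draws, iterations x chains.
#' @return scalar ESS.
#' @export
ess_bulk <- function(chains) {
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("ess_bulk requires at least 2 chains")
  z <- split_chains(chains)
  z[] <- rank_normalize(as.vector(z))
  n <- nrow(z)
  m <- ncol(z)
  if (n < 4L) stop("ess_bulk requires at least 8 iterations per chain")
  vars <- apply(z, 2, var)
  w <- mean(vars)
  means <- colMeans(z)
  var_plus <- (n - 1) / n * w + var(means)
  if (var_plus == 0) return(NA_real_)
  max_lag <- n - 1L
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(z[, j], lag.max = max_lag, type = "covariance",
             plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (w - rowMeans(acov)) / var_plus  # rho[1] is lag 0
  # Geyer initial positive monotone sequence over consecutive lag pairs
  # (lags 0+1, 2+3, ...): keep pairs while their sum is positive, force the
  # sums non-increasing, then tau = -rho_0 + 2 * sum of kept pair sums.
  n_pairs <- floor(length(rho) / 2)
  pair_sums <- numeric(0)
  for (k in seq_len(n_pairs)) {
    p <- rho[2 * k - 1] + rho[2 * k]
    if (p <= 0) break
    pair_sums <- c(pair_sums, p)
  }
  if (length(pair_sums) > 1L) pair_sums <- cummin(pair_sums)
  tau <- -rho[1] + 2 * sum(pair_sums)
  ess <- n * m / max(tau, 1 / (n * m))
  min(ess, n * m * log10(n * m))
}

#' Convergence diagnostics for a fitted discounting model
#'
#' Rank-normalized split R-hat and bulk effective sample size for every
#' monitored population-level parameter, with pass/warn flags at the
#' conventional thresholds (R-hat < 1.01, ESS > 1000).
#'
#' @param fit a `ptd_fit` from [fit_discount_model()], or an
#'   `coda::mcmc.list`.
#' @param params optional character vector restricting the parameters.
#' @return tibble with columns parameter, rhat, ess_bulk, rhat_ok, ess_ok.
#' @export
convergence_diagnostics <- function(fit, params = NULL) {
  ml <- if (inherits(fit, "ptd_fit")) fit$samples else fit
  if (!inherits(ml, "mcmc.list")) stop("fit must be a ptd_fit or coda::mcmc.list")
  if (length(ml) < 2L) stop("convergence diagnostics require at least 2 chains")
  vars <- coda::varnames(ml)
  if (!is.null(params)) vars <- intersect(vars, params)
  res <- lapply(vars, function(v) {
    ch <- sapply(ml, function(chain) as.numeric(chain[, v]))
    if (sd(as.vector(ch)) == 0) {
      return(tibble::tibble(parameter = v, rhat = NA_real_, ess_bulk = NA_real_))
    }
    tibble::tibble(parameter = v, rhat = rhat(ch), ess_bulk = ess_bulk(ch))
  })
  out <- do.call(rbind, res)
  out$rhat_ok <- !is.na(out$rhat) & out$rhat < 1.01
  out$ess_ok <- !is.na(out$ess_bulk) & out$ess_bulk > 1000
  out
}
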