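#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm qnorm quantile sd var cor lm coef confint
#'   pt rank acf binom.test setNames complete.cases aggregate dnorm density
#' @importFrom utils head tail
NULL

# Per-stage RNG streams derived from one master seed. Offsets are fixed so a
# pipeline run is reproducible stage by stage; results stay below 2^31.
derive_seed <- function(seed, stage) {
  offsets <- c(
    schedule = 11L, paths = 23L, panel = 37L, scales = 53L,
    fit_pos = 71L, fit_neg = 89L, ppc = 101L, score = 113L,
    inference = 127L, power = 139L
  )
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 7919 + offsets[[stage]]) %% 2147483647)
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("configuration error: `%s` must be an integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

check_psd <- function(m, name) {
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop(sprintf("`%s` must be a symmetric matrix", name), call. = FALSE)
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop(sprintf("`%s` is not positive semi-definite (min eigenvalue %.3g)",
                 name, min(ev)), call. = FALSE)
  }
  invisible(m)
}

# Map the valence argument ("positive"/"negative" or +1/-1) to the sign code
# used in the affect panel.
valence_code <- function(valence) {
  if (is.character(valence)) {
    valence <- match.arg(valence, c("positive", "negative"))
    return(if (valence == "positive") 1L else -1L)
  }
  if (!valence %in% c(1, -1)) stop("valence must be 'positive', 'negative', +1 or -1")
  as.integer(valence)
}

valence_label <- function(code) if (code > 0) "positive" else "negative"
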