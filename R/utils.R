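#' Within-subject z-scores
#'
#' Standardizes `x` to mean 0 and unit sample standard deviation (n - 1
#' denominator). Returns all-`NA` when the series is constant or has fewer
#' than two observations, so degenerate subjects surface as flagged rather
#' than as infinities.
#'
#' @param x Numeric vector.
#' @return Numeric vector of the same length.
#' @keywords internal
#' @noRd
zscore <- function(x) {
  n <- sum(!is.na(x))
  s <- stats::sd(x, na.rm = TRUE)
  if (n < 2L || !is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
  (x - mean(x, na.rm = TRUE)) / s
}

# round-half-up (base round() is round-half-even, which would bias the
# latent-to-Likert map at the .5 boundaries)
round_half_up <- function(x) floor(x + 0.5)

# deterministic fan-out of a master seed into stage-specific sub-seeds;
# kept strictly below 2^31 - 1 so the result is always a valid integer seed
derive_seed <- function(seed, salt) {
  m <- 2147483629
  as.integer((as.double(seed %% m) * 48271 + as.double(salt) * 9973 + 12345) %% m)
}

# evaluate `expr` with a local RNG state seeded at `seed`, leaving the
# caller's RNG untouched
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

stop_field <- function(field, msg) {
  abort(sprintf("invalid `%s`: %s", field, msg), class = "sleepmood_config_error")
}

# pooled (df-weighted) standard deviation of two samples, Cohen's-d denominator
pooled_sd <- function(y1, y0) {
  n1 <- length(y1); n0 <- length(y0)
  if (n1 + n0 < 3L) return(NA_real_)
  v1 <- if (n1 > 1L) stats::var(y1) else 0
  v0 <- if (n0 > 1L) stats::var(y0) else 0
  sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2))
}

# standardized mean difference of a covariate between treatment classes
smd <- function(x, tr) {
  x1 <- x[tr == 1L]; x0 <- x[tr == 0L]
  if (!length(x1) || !length(x0)) return(NA_real_)
  s <- pooled_sd(x1, x0)
  if (!is.finite(s)) return(NA_real_)
  if (s == 0) return(0)
  (mean(x1) - mean(x0)) / s
}

# two-sided percentile-bootstrap p-value for H0: statistic == 0
percentile_p <- function(boot_stats) {
  b <- boot_stats[is.finite(boot_stats)]
  if (!length(b)) return(NA_real_)
  lo <- (1 + sum(b <= 0)) / (length(b) + 1)
  hi <- (1 + sum(b >= 0)) / (length(b) + 1)
  min(1, 2 * min(lo, hi))
}
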