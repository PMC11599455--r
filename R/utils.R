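# Internal helpers shared across modules.

MONTH_DAYS <- 365.25 / 12  # fixed month length in days

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a stage seed from a master seed
#'
#' All randomness in a pipeline run flows from one master seed; each stage
#' draws its own seed deterministically so stages can be re-run in isolation.
#'
#' @param master integer master seed.
#' @param stage integer stage index (>= 1).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.numeric(stage))
  m <- 2147483647
  as.integer((abs(master) %% m * 48271 + 1009 * stage) %% (m - 1) + 1)
}

# Two-sample Kolmogorov-Smirnov statistic, no p-value machinery.
ks_statistic <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  w <- c(x, y)
  ord <- order(w)
  z <- cumsum(ifelse(ord <= nx, 1 / nx, -1 / ny))
  # with ties, the ecdf difference is defined only at distinct pooled values
  keep <- c(diff(w[ord]) != 0, TRUE)
  max(abs(z[keep]))
}

# Bootstrap p-value for the KS statistic: resample the pooled values under the
# null of a common distribution and count statistics at least as extreme.
ks_boot_p <- function(x, y, nboots) {
  nx <- length(x)
  ny <- length(y)
  if (nx == 0L || ny == 0L) return(1)
  if (stats::sd(c(x, y)) == 0) return(1)  # degenerate: identical constants
  obs <- ks_statistic(x, y)
  pooled <- c(x, y)
  n <- nx + ny
  hits <- 0L
  for (r in seq_len(nboots)) {
    idx <- sample.int(n, n, replace = TRUE)
    d <- ks_statistic(pooled[idx[seq_len(nx)]], pooled[idx[(nx + 1L):n]])
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  hits / nboots
}

# Paired t-test p-value on pair differences, with the degenerate conventions
# used for balance assessment: all differences zero -> perfectly balanced.
paired_t_p <- function(x_t, x_c) {
  d <- x_t - x_c
  if (length(d) < 2L) return(1)
  s <- stats::sd(d)
  if (s == 0) return(if (mean(d) == 0) 1 else 0)
  tt <- mean(d) / (s / sqrt(length(d)))
  2 * stats::pt(-abs(tt), df = length(d) - 1L)
}

# Evaluate a right-continuous step function S(t) defined by jump times and
# post-jump values; S = 1 before the first jump.
step_eval <- function(times, values, t) {
  idx <- findInterval(t, times)
  c(1, values)[idx + 1L]
}

# Left limit S(t-): value just before t.
step_eval_left <- function(times, values, t) {
  idx <- findInterval(t, times, left.open = TRUE)
  c(1, values)[idx + 1L]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
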