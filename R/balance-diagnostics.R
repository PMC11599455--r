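# Covariate balance diagnostics before and after matching: absolute
# standardized mean differences, variance ratios, and Kolmogorov-Smirnov
# statistics with bootstrap p-values.

#' Absolute standardized mean difference
#'
#' `|mean(x_t) - mean(x_c)| / sd_ref`, where `sd_ref` is computed once on the
#' pooled pre-match sample and held fixed post-match so that pre- and
#' post-match SMDs are comparable.
#'
#' @param x_t,x_c value vectors for treated and control.
#' @param sd_ref positive reference standard deviation.
#' @return nonnegative scalar.
#' @export
standardized_mean_difference <- function(x_t, x_c, sd_ref) {
  d <- mean(x_t) - mean(x_c)
  if (sd_ref == 0) {
    if (d == 0) return(0)
    stop("sd_ref is 0 with unequal means; SMD undefined")
  }
  abs(d) / sd_ref
}

# Pooled pre-match reference SD: sqrt of the average of the two arm
# variances; for a binary covariate, sqrt(p(1-p)) of the pooled proportion.
reference_sd <- function(x_t, x_c, binary = NULL) {
  if (is.null(binary)) binary <- length(unique(c(x_t, x_c))) <= 2L
  if (binary) {
    p <- mean(c(x_t, x_c))
    sqrt(p * (1 - p))
  } else {
    sqrt((stats::var(x_t) + stats::var(x_c)) / 2)
  }
}

#' Orientation-free variance ratio
#'
#' `max(r, 1/r)` with `r = var(x_t)/var(x_c)`, so the conventional "< 2"
#' balance criterion does not depend on which arm is in the numerator.
#'
#' @param x_t,x_c value vectors with positive variance.
#' @return a ratio >= 1.
#' @export
variance_ratio <- function(x_t, x_c) {
  vt <- stats::var(x_t); vc <- stats::var(x_c)
  if (vt == 0 || vc == 0) stop("variance ratio undefined for zero-variance input")
  r <- vt / vc
  max(r, 1 / r)
}

#' Balance table before and after matching
#'
#' One row per balance column (one-hot covariates plus squared-age and
#' age-by-sex terms when present): pre-match and post-match absolute SMD
#' (both standardized by the pooled pre-match SD), matched variance ratio and
#' Kolmogorov-Smirnov statistic/bootstrap p-value for continuous columns, and
#' flags for the conventional SMD < 0.1 and variance ratio < 2 criteria.
#'
#' @param cohort an `rw_cohort`.
#' @param match an `rw_match` from [genetic_search()] or
#'   [match_with_weights()].
#' @param config the [matching_config()] used (supplies covariate list and
#'   KS bootstrap replicates).
#' @return a data.frame of class `rw_balance`.
#' @export
balance_report <- function(cohort, match, config) {
  if (nrow(match$pairs) == 0L) stop("empty match")
  prep <- match_prep(cohort, config)
  ti <- match$treated_rows %||% match(match$pairs$treated_id, cohort$id)
  ci <- match$control_rows %||% match(match$pairs$control_id, cohort$id)
  Fm <- prep$fitness
  trt_all <- prep$treated
  ctl_all <- which(arm01(cohort) == 0L)
  rows <- lapply(seq_len(ncol(Fm)), function(k) {
    x <- Fm[, k]
    cont <- prep$is_cont[k]
    sd_ref <- reference_sd(x[trt_all], x[ctl_all], binary = !cont)
    smd_un <- standardized_mean_difference(x[trt_all], x[ctl_all], sd_ref)
    smd_m <- standardized_mean_difference(x[ti], x[ci], sd_ref)
    vr <- if (cont) variance_ratio(x[ti], x[ci]) else NA_real_
    ks <- if (cont) ks_statistic(x[ti], x[ci]) else NA_real_
    ksp <- if (cont) ks_boot_p(x[ti], x[ci], config$ks_boot_reps) else NA_real_
    data.frame(covariate = colnames(Fm)[k], continuous = cont,
               smd_unmatched = smd_un, smd_matched = smd_m,
               variance_ratio_matched = vr,
               ks_stat = ks, ks_p_matched = ksp,
               flag_smd = smd_m >= 0.1,
               flag_variance_ratio = !is.na(vr) & vr >= 2,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("rw_balance", "data.frame")
  out
}
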