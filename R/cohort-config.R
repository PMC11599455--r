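#' Describe one baseline covariate of the synthetic cohort
#'
#' @param name column name in the generated cohort.
#' @param kind one of `"continuous"`, `"binary"`, `"categorical"`.
#' @param exact_match logical; exact-matching covariates define the strata
#'   within which nearest-neighbour matching is constrained.
#' @param ... distribution parameters. Continuous: `dist` (`"normal"` or
#'   `"lognormal"`), `mean`/`sd` or `meanlog`/`sdlog`. Binary: `p`. Categorical:
#'   `levels` (character) and `probs`. Binary covariates may carry a
#'   `joint_group` label: all binaries sharing a label are mutually exclusive
#'   indicators drawn from a single multinomial (remaining mass is the implicit
#'   reference category).
#' @return an object of class `rw_covariate_spec`.
#' @export
covariate_spec <- function(name, kind = c("continuous", "binary", "categorical"),
                           exact_match = FALSE, ...) {
  kind <- match.arg(kind)
  pars <- list(...)
  if (kind == "binary") {
    stopifnot(!is.null(pars$p), pars$p >= 0, pars$p <= 1)
  } else if (kind == "categorical") {
    stopifnot(length(pars$levels) >= 2L, length(pars$probs) == length(pars$levels),
              all(pars$probs >= 0), abs(sum(pars$probs) - 1) < 1e-8)
  } else {
    pars$dist <- pars$dist %||% "normal"
  }
  structure(c(list(name = name, kind = kind, exact_match = isTRUE(exact_match)), pars),
            class = "rw_covariate_spec")
}

default_covariate_specs <- function() {
  list(
    covariate_spec("age", "continuous", mean = 69, sd = 10.2),
    covariate_spec("sex_male", "binary", p = 0.452),
    covariate_spec("days_since_dx", "continuous", dist = "lognormal",
                   meanlog = 4.4, sdlog = 1.0),
    covariate_spec("baseline_cost", "continuous", dist = "lognormal",
                   meanlog = 7.93, sdlog = 0.8),
    covariate_spec("prior_lines", "categorical", exact_match = TRUE,
                   levels = c("0", "1", "2plus"), probs = c(0.85, 0.13, 0.02)),
    covariate_spec("prior_surgery", "binary", exact_match = TRUE, p = 0.085),
    covariate_spec("vch", "binary", exact_match = TRUE, p = 0.21, joint_group = "authority"),
    covariate_spec("fraser", "binary", p = 0.33, joint_group = "authority"),
    covariate_spec("interior", "binary", p = 0.19, joint_group = "authority")
  )
}

default_assignment_coefficients <- function() {
  c(age = -0.016, sex_male = 0, days_since_dx = 0.0004, baseline_cost = 0,
    prior_lines.1 = 0.45, prior_lines.2plus = 0.55, prior_surgery = 0.95,
    vch = 0.60, fraser = -0.15, interior = 0.10)
}

default_survival_coefficients <- function() {
  c(age = 0.018, sex_male = 0.25, days_since_dx = 0.0004, baseline_cost = 0,
    prior_lines.1 = 0.20, prior_lines.2plus = 0.35, prior_surgery = -0.30,
    vch = 0, fraser = 0, interior = 0)
}

#' Configuration of the synthetic administrative cohort generator
#'
#' Defaults emulate a two-arm molecular-testing cohort observed through linked
#' administrative data: about 2,172 advanced-cancer patients of whom 43.2%
#' receive the newer (multi-gene panel) test, confounded treatment assignment,
#' Weibull proportional-hazards survival with a small protective treatment
#' effect (HR 0.932), uniform-accrual administrative censoring plus a small
#' dropout hazard yielding roughly 26-32% censoring, and monthly cost accruals
#' dominated by systemic therapy with an end-of-life spike and per-test costs
#' of $1200 (panel) versus $228 (single-gene), in 2021 CAD.
#'
#' @param n_patients cohort size (>= 20).
#' @param treated_fraction_target marginal probability of treatment; the
#'   assignment-model intercept is calibrated to hit it on the drawn covariates.
#' @param covariate_specs list of [covariate_spec()] objects.
#' @param assignment_coefficients named log-odds contributions per one-hot
#'   covariate column (covariates are centred at their theoretical means).
#' @param survival_coefficients named log-hazard contributions per one-hot
#'   covariate column (centred likewise); these induce the confounding.
#' @param weibull_shape,weibull_scale_control Weibull shape and control-arm
#'   scale (days) of the baseline survival distribution.
#' @param treatment_log_hazard_ratio log hazard ratio of treatment.
#' @param censoring list with `accrual_window_days` (uniform study entry),
#'   `admin_cutoff_days` (administrative end of follow-up, measured from the
#'   start of accrual) and `dropout_rate_per_year` (exponential loss to
#'   follow-up, e.g. deregistration from the public insurer).
#' @param cost_model list with `baseline_monthly_mean_log`,
#'   `baseline_monthly_sd_log`, `patient_effect_share` (share of the log-cost
#'   variance that is between-patient), `systemic_therapy_monthly_cost`,
#'   `systemic_therapy_uptake_by_arm` (control, treated),
#'   `eol_spike_cost`, `eol_spike_months`, `test_cost_treated`,
#'   `test_cost_control`, `oop_monthly_meanlog`, `oop_monthly_sdlog`
#'   (out-of-pocket drug costs used by the societal-perspective scenario).
#' @param egfr_positive_fraction_by_arm,egfr_inconclusive_fraction_by_arm
#'   length-2 vectors (control, treated) of test-result fractions.
#' @param seed integer seed; generation is bit-reproducible given the config.
#' @return an object of class `rw_cohort_config`.
#' @export
cohort_config <- function(n_patients = 2172,
                          treated_fraction_target = 0.432,
                          covariate_specs = default_covariate_specs(),
                          assignment_coefficients = default_assignment_coefficients(),
                          survival_coefficients = default_survival_coefficients(),
                          weibull_shape = 1.0,
                          weibull_scale_control = 500,
                          treatment_log_hazard_ratio = log(0.932),
                          censoring = list(accrual_window_days = 852,
                                           admin_cutoff_days = 1217,
                                           dropout_rate_per_year = 0.06),
                          cost_model = list(baseline_monthly_mean_log = 7.6,
                                            baseline_monthly_sd_log = 0.9,
                                            patient_effect_share = 0.6,
                                            systemic_therapy_monthly_cost = 6000,
                                            systemic_therapy_uptake_by_arm = c(0.50, 0.52),
                                            eol_spike_cost = 12000,
                                            eol_spike_months = 2,
                                            test_cost_treated = 1200,
                                            test_cost_control = 228,
                                            oop_monthly_meanlog = 4.6,
                                            oop_monthly_sdlog = 0.8),
                          egfr_positive_fraction_by_arm = c(0.205, 0.209),
                          egfr_inconclusive_fraction_by_arm = c(0.149, 0.042),
                          seed = 1L) {
  cfg <- structure(list(
    n_patients = n_patients,
    treated_fraction_target = treated_fraction_target,
    covariate_specs = covariate_specs,
    assignment_coefficients = assignment_coefficients,
    survival_coefficients = survival_coefficients,
    weibull_shape = weibull_shape,
    weibull_scale_control = weibull_scale_control,
    treatment_log_hazard_ratio = treatment_log_hazard_ratio,
    censoring = censoring,
    cost_model = cost_model,
    egfr_positive_fraction_by_arm = egfr_positive_fraction_by_arm,
    egfr_inconclusive_fraction_by_arm = egfr_inconclusive_fraction_by_arm,
    seed = as.integer(seed)
  ), class = "rw_cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "rw_cohort_config"))
  if (cfg$n_patients < 20) stop("n_patients must be at least 20 (too small to match)")
  probs <- c(cfg$treated_fraction_target,
             cfg$egfr_positive_fraction_by_arm, cfg$egfr_inconclusive_fraction_by_arm,
             cfg$cost_model$systemic_therapy_uptake_by_arm)
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (cfg$weibull_shape <= 0) stop("weibull_shape must be positive")
  cs <- cfg$censoring
  if (is.finite(cs$admin_cutoff_days) && cs$admin_cutoff_days < cs$accrual_window_days)
    stop("admin_cutoff_days must be at least accrual_window_days")
  if (cs$dropout_rate_per_year < 0) stop("dropout_rate_per_year must be nonnegative")
  if (cfg$cost_model$eol_spike_months < 1) stop("eol_spike_months must be at least 1")
  n_exact <- sum(vapply(cfg$covariate_specs, function(s) s$exact_match, logical(1)))
  if (n_exact < 1) stop("at least one covariate must have exact_match = TRUE")
  invisible(cfg)
}

# Theoretical mean of each one-hot covariate column, used to centre the
# assignment and survival linear predictors.
covariate_centers <- function(specs) {
  out <- c()
  for (s in specs) {
    if (s$kind == "continuous") {
      m <- if (identical(s$dist, "lognormal")) exp(s$meanlog + s$sdlog^2 / 2) else s$mean
      out[s$name] <- m
    } else if (s$kind == "binary") {
      out[s$name] <- s$p
    } else {
      for (k in seq_along(s$levels)[-1L])
        out[paste(s$name, s$levels[k], sep = ".")] <- s$probs[k]
    }
  }
  out
}
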