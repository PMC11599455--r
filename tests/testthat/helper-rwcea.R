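# Shared fixtures, all built in code.

# A small, quickly generated cohort configuration.
quick_config <- function(n = 400, seed = 1, ...) {
  cohort_config(n_patients = n, seed = seed, ...)
}

# Configuration with every censoring mechanism disabled.
no_censoring_config <- function(n = 400, seed = 1, ...) {
  cohort_config(n_patients = n, seed = seed,
                censoring = list(accrual_window_days = 852,
                                 admin_cutoff_days = Inf,
                                 dropout_rate_per_year = 0),
                ...)
}

# Symmetric-arm configuration: no treatment effect on survival or costs
# (equal test costs and systemic uptake), used for null-recovery tests.
symmetric_config <- function(n = 400, seed = 1, ...) {
  cm <- cohort_config()$cost_model
  cm$test_cost_treated <- cm$test_cost_control
  cm$systemic_therapy_uptake_by_arm <- c(0.5, 0.5)
  cohort_config(n_patients = n, seed = seed,
                treatment_log_hazard_ratio = 0, cost_model = cm, ...)
}

# Small matching configuration for fast tests.
quick_matching_config <- function(cohort, ...) {
  args <- list(covariate_names = cohort_covariates(cohort),
               exact_match_names = c("prior_lines", "prior_surgery", "vch"),
               population_size = 10L, max_generations = 3L,
               stall_generations = 2L, ks_boot_reps = 60L, seed = 7L)
  over <- list(...)
  for (nm in names(over)) args[[nm]] <- over[[nm]]
  do.call(matching_config, args)
}

# The printed four-patient toy follow-up dataset used by the hand oracles:
# A dies day 45, B censored day 50, C dies day 70, D dies day 100.
toy_followup <- function() {
  data.frame(id = c("A", "B", "C", "D"),
             time = c(45, 50, 70, 100),
             event = c("death", "censored", "death", "death"),
             stringsAsFactors = FALSE)
}

# Build a minimal cohort data.frame by hand (bypassing the generator) with
# constant monthly costs, for estimator toy tests.
manual_cohort <- function(obs_time, event, arm, monthly_cost = 1000,
                          n_months = 36) {
  n <- length(obs_time)
  L <- 365.25 / 12
  costs <- matrix(0, n, n_months)
  for (m in seq_len(n_months)) {
    frac <- pmin(pmax((obs_time - (m - 1) * L) / L, 0), 1)
    costs[, m] <- monthly_cost * frac
  }
  colnames(costs) <- sprintf("cost_m%02d", seq_len(n_months))
  df <- data.frame(id = seq_len(n), arm = arm,
                   survival_time_days = ifelse(event == "death", obs_time, Inf),
                   censor_time_days = ifelse(event == "censored", obs_time, Inf),
                   obs_time_days = obs_time, event = event,
                   stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(costs))
  class(df) <- c("rw_cohort", "data.frame")
  df
}
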