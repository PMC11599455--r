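# Synthetic administrative cohort: covariates, confounded assignment, Weibull
# survival, accrual/dropout censoring, monthly cost accruals, and an oracle for
# the true (censoring-free) estimands.

N_COST_MONTHS <- 36L

# Draw the raw covariate data.frame from the specs. Binaries sharing a
# joint_group are mutually exclusive indicators of one multinomial.
draw_covariates <- function(specs, n) {
  out <- list()
  groups <- list()
  for (s in specs) {
    if (s$kind == "binary" && !is.null(s$joint_group)) {
      groups[[s$joint_group]] <- c(groups[[s$joint_group]], list(s))
      out[[s$name]] <- NA_real_  # placeholder, keeps column order
      next
    }
    out[[s$name]] <- switch(s$kind,
      continuous = if (identical(s$dist, "lognormal"))
        stats::rlnorm(n, s$meanlog, s$sdlog) else stats::rnorm(n, s$mean, s$sd),
      binary = as.numeric(stats::runif(n) < s$p),
      categorical = {
        lev <- s$levels
        factor(lev[1L + findInterval(stats::runif(n), cumsum(s$probs[-length(s$probs)]))],
               levels = lev)
      })
  }
  for (g in groups) {
    p <- vapply(g, function(s) s$p, numeric(1))
    if (sum(p) > 1) stop("joint_group binary probabilities exceed 1")
    u <- stats::runif(n)
    edges <- cumsum(p)
    cat_idx <- findInterval(u, c(0, edges), left.open = TRUE)  # 1..k inside, k+1 = reference
    for (k in seq_along(g))
      out[[g[[k]]$name]] <- as.numeric(cat_idx == k)
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' One-hot design matrix for a set of covariates
#'
#' Categorical covariates are expanded to indicator columns named
#' `name.level` with the first (reference) level dropped; continuous and
#' binary covariates pass through unchanged.
#'
#' @param data data.frame holding the covariate columns.
#' @param covariate_names character vector of covariate columns to expand.
#' @return numeric matrix with one row per patient.
#' @export
one_hot_matrix <- function(data, covariate_names) {
  cols <- list()
  for (nm in covariate_names) {
    x <- data[[nm]]
    if (is.null(x)) stop("covariate not found in data: ", nm)
    if (is.factor(x) || is.character(x)) {
      x <- as.factor(x)
      for (lev in levels(x)[-1L])
        cols[[paste(nm, lev, sep = ".")]] <- as.numeric(x == lev)
    } else {
      cols[[nm]] <- as.numeric(x)
    }
  }
  do.call(cbind, cols)
}

# Linear predictor from named coefficients over the one-hot matrix, with
# covariates centred at their theoretical means.
centered_lp <- function(X, coefs, centers) {
  lp <- numeric(nrow(X))
  for (nm in names(coefs)) {
    if (coefs[[nm]] == 0) next
    if (!nm %in% colnames(X)) stop("coefficient for unknown column: ", nm)
    ctr <- if (nm %in% names(centers)) centers[[nm]] else 0
    lp <- lp + coefs[[nm]] * (X[, nm] - ctr)
  }
  lp
}

# Monthly cost matrix (n x 36) given death times, observed times and arm.
# `observed` limits accrual (censoring truncates observation); the end-of-life
# spike attaches to the death time and is recorded only when death is observed.
build_cost_matrix <- function(cfg, arm01, death_time, obs_time, z_patient,
                              eps_month, uptake_u, spike_observed) {
  cm <- cfg$cost_model
  n <- length(death_time)
  L <- MONTH_DAYS
  sd_pat <- cm$baseline_monthly_sd_log * sqrt(cm$patient_effect_share)
  sd_mon <- cm$baseline_monthly_sd_log * sqrt(1 - cm$patient_effect_share)
  base <- exp(cm$baseline_monthly_mean_log + sd_pat * z_patient + sd_mon * eps_month)
  uptake <- cm$systemic_therapy_uptake_by_arm[arm01 + 1L]
  on_tx <- as.numeric(uptake_u < uptake)
  starts <- (seq_len(N_COST_MONTHS) - 1L) * L
  frac <- pmin(pmax((obs_time - rep(starts, each = n)) / L, 0), 1)
  dim(frac) <- c(n, N_COST_MONTHS)
  costs <- (base + on_tx * cm$systemic_therapy_monthly_cost) * frac
  # end-of-life spike: equal shares over the eol_spike_months months ending at
  # the month of death, observed only if the death itself is observed
  k <- cm$eol_spike_months
  if (cm$eol_spike_cost > 0) {
    dm <- ceiling(death_time / L)
    for (off in seq_len(k) - 1L) {
      m <- dm - off
      sel <- spike_observed & m >= 1L & m <= N_COST_MONTHS
      if (any(sel))
        costs[cbind(which(sel), m[sel])] <-
          costs[cbind(which(sel), m[sel])] + cm$eol_spike_cost / k
    }
  }
  test_cost <- ifelse(arm01 == 1L, cm$test_cost_treated, cm$test_cost_control)
  costs[, 1L] <- costs[, 1L] + test_cost
  colnames(costs) <- sprintf("cost_m%02d", seq_len(N_COST_MONTHS))
  costs
}

build_oop_matrix <- function(cfg, obs_time, eps_oop) {
  cm <- cfg$cost_model
  n <- length(obs_time)
  L <- MONTH_DAYS
  starts <- (seq_len(N_COST_MONTHS) - 1L) * L
  frac <- pmin(pmax((obs_time - rep(starts, each = n)) / L, 0), 1)
  dim(frac) <- c(n, N_COST_MONTHS)
  oop <- exp(cm$oop_monthly_meanlog + cm$oop_monthly_sdlog * eps_oop) * frac
  colnames(oop) <- sprintf("oop_m%02d", seq_len(N_COST_MONTHS))
  oop
}

#' Generate a synthetic two-arm cohort
#'
#' Treatment assignment follows a logistic model on the covariates (inducing
#' nonzero pre-match standardized mean differences), survival a Weibull
#' proportional-hazards model, censoring the minimum of administrative
#' follow-up under uniform accrual and exponential dropout, and monthly cost
#' accruals include a systemic-therapy component, an end-of-life spike
#' attached to the death time, and the per-test cost in month 1.
#'
#' @param config an [cohort_config()] object.
#' @return a data.frame of class `rw_cohort`: one row per patient with columns
#'   `id`, `arm` (`"treated"`/`"control"`), the covariates, `egfr_result`,
#'   `survival_time_days`, `censor_time_days`, `obs_time_days`, `event`
#'   (`"death"`/`"censored"`), monthly observed cost columns
#'   `cost_m01..cost_m36` and out-of-pocket columns `oop_m01..oop_m36`. The
#'   generating config is attached as attribute `config`.
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  n <- cfg$n_patients
  set.seed(cfg$seed)
  cov_df <- draw_covariates(cfg$covariate_specs, n)
  cov_names <- vapply(cfg$covariate_specs, function(s) s$name, character(1))
  X <- one_hot_matrix(cov_df, cov_names)
  centers <- covariate_centers(cfg$covariate_specs)

  # assignment: intercept calibrated so the mean assignment probability hits
  # the target treated fraction on the drawn covariates
  lp <- centered_lp(X, cfg$assignment_coefficients, centers)
  f <- function(a0) mean(stats::plogis(a0 + lp)) - cfg$treated_fraction_target
  a0 <- stats::uniroot(f, c(-25, 25))$root
  arm01 <- as.integer(stats::runif(n) < stats::plogis(a0 + lp))
  if (min(sum(arm01), n - sum(arm01)) < 10)
    stop("degenerate cohort: assignment model yields an arm with < 10 patients")

  # Weibull PH survival: S(t | x) = exp(-(t / scale)^shape * exp(eta))
  eta <- arm01 * cfg$treatment_log_hazard_ratio +
    centered_lp(X, cfg$survival_coefficients, centers)
  E <- stats::rexp(n)
  death <- cfg$weibull_scale_control * (E / exp(eta))^(1 / cfg$weibull_shape)

  # censoring: uniform accrual against an administrative cutoff plus dropout
  cs <- cfg$censoring
  entry <- stats::runif(n, 0, cs$accrual_window_days)
  admin <- if (is.finite(cs$admin_cutoff_days)) cs$admin_cutoff_days - entry else Inf
  drop_t <- if (cs$dropout_rate_per_year > 0)
    stats::rexp(n, rate = cs$dropout_rate_per_year / 365.25) else rep(Inf, n)
  cens <- pmin(admin, drop_t)
  obs <- pmin(death, cens)
  event <- ifelse(death <= cens, "death", "censored")

  z_pat <- if ("baseline_cost" %in% names(cov_df)) {
    lx <- log(cov_df$baseline_cost)
    as.numeric(scale(lx))
  } else stats::rnorm(n)
  eps_month <- matrix(stats::rnorm(n * N_COST_MONTHS), n, N_COST_MONTHS)
  uptake_u <- stats::runif(n)
  costs <- build_cost_matrix(cfg, arm01, death, obs, z_pat, eps_month, uptake_u,
                             spike_observed = event == "death")
  eps_oop <- matrix(stats::rnorm(n * N_COST_MONTHS), n, N_COST_MONTHS)
  oop <- build_oop_matrix(cfg, obs, eps_oop)

  u_egfr <- stats::runif(n)
  p_pos <- cfg$egfr_positive_fraction_by_arm[arm01 + 1L]
  p_inc <- cfg$egfr_inconclusive_fraction_by_arm[arm01 + 1L]
  egfr <- ifelse(u_egfr < p_pos, "positive",
                 ifelse(u_egfr < p_pos + p_inc, "inconclusive", "negative"))

  out <- data.frame(id = seq_len(n),
                    arm = ifelse(arm01 == 1L, "treated", "control"),
                    cov_df,
                    egfr_result = egfr,
                    survival_time_days = death,
                    censor_time_days = cens,
                    obs_time_days = obs,
                    event = event,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(costs), as.data.frame(oop))
  attr(out, "config") <- cfg
  attr(out, "covariate_names") <- cov_names
  class(out) <- c("rw_cohort", "data.frame")
  out
}

#' Covariate names of a cohort
#' @param cohort an `rw_cohort` (or a data.frame with the attribute set).
#' @return character vector.
#' @export
cohort_covariates <- function(cohort) {
  nm <- attr(cohort, "covariate_names")
  if (is.null(nm)) stop("cohort carries no covariate_names attribute")
  nm
}

event01 <- function(cohort) as.integer(cohort$event == "death")
arm01 <- function(cohort) as.integer(cohort$arm == "treated")

cost_matrix <- function(cohort, n_intervals = N_COST_MONTHS, prefix = "cost_m") {
  cols <- sprintf("%s%02d", prefix, seq_len(n_intervals))
  missing <- setdiff(cols, names(cohort))
  if (length(missing)) stop("missing cost columns: ", paste(missing, collapse = ", "))
  as.matrix(cohort[, cols])
}

#' True estimands of a cohort configuration
#'
#' Simulates a large censoring-free cohort under common random numbers (the
#' same patients are pushed through both arms, so symmetric configurations
#' yield exactly zero increments) and returns discounted 3-year mean costs and
#' life-years per arm under the same monthly-interval discounting convention
#' used by the estimator.
#'
#' @param config an [cohort_config()] object.
#' @param n_oracle number of simulated patients (>= 1e4; 1e5 recommended).
#' @param horizon_years,annual_discount_rate estimand conventions, matching
#'   [build_grid()].
#' @return a list of class `rw_true_estimands` with per-arm means,
#'   `true_delta_c`, `true_delta_e` and `true_hazard_ratio`.
#' @export
true_estimands <- function(config, n_oracle = 1e5, horizon_years = 3,
                           annual_discount_rate = 0.015) {
  validate_cohort_config(config)
  if (n_oracle < 1e4) stop("n_oracle must be at least 1e4 for a stable oracle")
  cfg <- config
  set.seed(derive_seed(cfg$seed, 97L))
  n <- as.integer(n_oracle)
  cov_df <- draw_covariates(cfg$covariate_specs, n)
  cov_names <- vapply(cfg$covariate_specs, function(s) s$name, character(1))
  X <- one_hot_matrix(cov_df, cov_names)
  centers <- covariate_centers(cfg$covariate_specs)
  eta_x <- centered_lp(X, cfg$survival_coefficients, centers)
  E <- stats::rexp(n)
  z_pat <- if ("baseline_cost" %in% names(cov_df))
    as.numeric(scale(log(cov_df$baseline_cost))) else stats::rnorm(n)
  eps_month <- matrix(stats::rnorm(n * N_COST_MONTHS), n, N_COST_MONTHS)
  uptake_u <- stats::runif(n)

  grid <- build_grid(horizon_years, annual_discount_rate)
  res <- list()
  for (a in c(0L, 1L)) {
    eta <- a * cfg$treatment_log_hazard_ratio + eta_x
    death <- cfg$weibull_scale_control * (E / exp(eta))^(1 / cfg$weibull_shape)
    costs <- build_cost_matrix(cfg, rep(a, n), death, death, z_pat, eps_month,
                               uptake_u, spike_observed = rep(TRUE, n))
    ad <- alive_days_matrix(death, grid)
    j <- seq_len(grid$n_intervals)
    res[[a + 1L]] <- list(
      cost = sum(grid$discount_factor * colMeans(costs[, j, drop = FALSE])),
      ly = sum(grid$discount_factor * colMeans(ad)) / 365.25)
  }
  structure(list(
    true_mean_discounted_cost_by_arm = c(control = res[[1]]$cost, treated = res[[2]]$cost),
    true_mean_discounted_ly_by_arm = c(control = res[[1]]$ly, treated = res[[2]]$ly),
    true_delta_c = res[[2]]$cost - res[[1]]$cost,
    true_delta_e = res[[2]]$ly - res[[1]]$ly,
    true_hazard_ratio = exp(cfg$treatment_log_hazard_ratio),
    n_oracle = n), class = "rw_true_estimands")
}
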