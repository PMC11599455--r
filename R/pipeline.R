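# Orchestration: simulate -> match -> balance -> survival -> estimate -> cea
# -> report, all driven by one config and one master seed.

#' Pipeline run configuration
#'
#' @param out_dir output directory; created if absent.
#' @param cohort an [cohort_config()] (its `seed` is overridden by a seed
#'   derived from `master_seed`).
#' @param horizon_years,annual_discount_rate estimation conventions.
#' @param wtp willingness-to-pay thresholds.
#' @param B bootstrap replicates.
#' @param master_seed one seed from which every stage deterministically
#'   derives its own.
#' @param scenarios sensitivity scenarios to run (`NULL` or empty for none).
#' @param matching named list of [matching_config()] overrides (e.g.
#'   `population_size`, `max_generations`, `ks_boot_reps`).
#' @param run_matching set `FALSE` to self-pair a pre-paired cohort (each
#'   treated patient must then already have a `pair_id`); normally `TRUE`.
#' @return an object of class `rw_run_config`.
#' @export
run_config <- function(out_dir = "results",
                       cohort = cohort_config(),
                       horizon_years = 3,
                       annual_discount_rate = 0.015,
                       wtp = c(50000, 100000),
                       B = 1000L,
                       master_seed = 1L,
                       scenarios = character(0),
                       matching = list(),
                       run_matching = TRUE) {
  structure(list(out_dir = out_dir, cohort = cohort,
                 horizon_years = horizon_years,
                 annual_discount_rate = annual_discount_rate,
                 wtp = wtp, B = as.integer(B),
                 master_seed = as.integer(master_seed),
                 scenarios = scenarios, matching = matching,
                 run_matching = isTRUE(run_matching)),
            class = "rw_run_config")
}

#' Load a pipeline configuration from YAML
#'
#' Scalar fields override [run_config()] defaults; `cohort:` entries override
#' [cohort_config()] defaults.
#'
#' @param path YAML file path.
#' @return an `rw_run_config`.
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cc_over <- y$cohort %||% list()
  cc <- do.call(cohort_config, cc_over)
  args <- y[setdiff(names(y), "cohort")]
  do.call(run_config, c(list(cohort = cc), args))
}

cohort_schema_columns <- function() {
  c("id", "arm", "survival_time_days", "censor_time_days", "obs_time_days", "event")
}

#' Write a cohort to CSV with a JSON sidecar
#'
#' Monthly costs are stored as wide columns `cost_m01..cost_m36`; the sidecar
#' `<path>.json` records the covariate names and generating configuration so
#' a round-trip preserves the cohort's metadata.
#'
#' @param cohort an `rw_cohort`.
#' @param path CSV destination.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  side <- list(covariate_names = attr(cohort, "covariate_names"),
               config = attr(cohort, "config"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Validates the schema (required identifier, arm, time and event columns;
#' numeric nonnegative costs and times) naming the offending column and row
#' in errors. Missing trailing cost cells are parsed as zero accrual. If the
#' JSON sidecar written by [write_cohort_csv()] is present its metadata is
#' re-attached.
#'
#' @param path CSV file path.
#' @return an `rw_cohort`.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cohort_schema_columns(), names(df))
  if (length(missing))
    stop("cohort CSV is missing required columns: ", paste(missing, collapse = ", "))
  for (col in c("survival_time_days", "censor_time_days", "obs_time_days")) {
    x <- df[[col]]
    if (!is.numeric(x)) stop("column ", col, " must be numeric")
    if (anyNA(x)) stop("column ", col, " has a missing value at row ", which(is.na(x))[1])
    if (any(x < 0)) stop("column ", col, " has a negative time at row ", which(x < 0)[1])
  }
  cost_cols <- grep("^(cost|oop)_m[0-9]+$", names(df), value = TRUE)
  for (col in cost_cols) {
    x <- df[[col]]
    if (is.character(x) && all(x %in% c("", NA))) x <- rep(NA_real_, length(x))
    if (!is.numeric(x) && !all(is.na(x))) stop("column ", col, " must be numeric")
    x <- as.numeric(x)
    x[is.na(x)] <- 0  # trailing empties after death/censoring: zero accrual
    if (any(x < 0)) stop("column ", col, " has a negative cost at row ", which(x < 0)[1])
    df[[col]] <- x
  }
  if (!all(df$event %in% c("death", "censored")))
    stop("column event must be 'death' or 'censored'")
  side_path <- paste0(path, ".json")
  if (file.exists(side_path)) {
    side <- jsonlite::fromJSON(side_path, simplifyVector = TRUE)
    attr(df, "covariate_names") <- side$covariate_names
    attr(df, "config") <- side$config
  }
  class(df) <- c("rw_cohort", "data.frame")
  df
}

matching_config_from_cohort <- function(cohort, overrides = list(), seed = 1L) {
  specs <- attr(cohort, "config")$covariate_specs
  cov_names <- cohort_covariates(cohort)
  exact <- if (!is.null(specs))
    cov_names[vapply(specs, function(s) isTRUE(s$exact_match), logical(1))]
  else character(0)
  args <- list(covariate_names = cov_names, exact_match_names = exact, seed = seed)
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(matching_config, args)
}

stage <- function(name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(force(expr), error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  message(sprintf("[rwcea] stage=%s elapsed=%.1fs", name, proc.time()[["elapsed"]] - t0))
  res
}

#' Run the full analysis pipeline
#'
#' simulate -> match -> balance -> survival -> IPCW estimation -> bootstrap
#' CEA (-> sensitivity suite), writing every stage's artifact under
#' `out_dir`: `cohort.csv` (+ JSON sidecar), `pairs.csv`, `weights.json`,
#' `balance.csv`, `survival_curves.csv`, `survival_fit.json`,
#' `estimates.json`, `cea_draws.csv`, `ceac.csv`, `summary.json`,
#' `sensitivity.csv` and a Markdown `report.md`. A rerun with the same
#' config and master seed is bit-identical.
#'
#' @param rc an [run_config()] object.
#' @return invisibly, a list with the stage objects and output paths.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "rw_run_config"))
  dir.create(rc$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(rc$out_dir, f)

  ccfg <- rc$cohort
  ccfg$seed <- derive_seed(rc$master_seed, 1L)
  cohort <- stage("simulate", {
    ch <- generate_cohort(ccfg)
    write_cohort_csv(ch, pth("cohort.csv"))
    ch
  })

  mc <- matching_config_from_cohort(cohort, rc$matching,
                                    seed = derive_seed(rc$master_seed, 2L))
  match <- stage("match", {
    m <- if (rc$run_matching) genetic_search(cohort, mc)
    else self_pair_match(cohort)
    utils::write.csv(m$pairs, pth("pairs.csv"), row.names = FALSE)
    jsonlite::write_json(list(weights = as.list(m$weight_vector),
                              n_matched = m$n_matched,
                              fitness_trace = m$fitness_trace),
                         pth("weights.json"), auto_unbox = TRUE, digits = NA)
    m
  })

  balance <- stage("balance", {
    b <- balance_report(cohort, match, mc)
    utils::write.csv(b, pth("balance.csv"), row.names = FALSE)
    b
  })

  surv <- stage("survival", {
    rows <- match(c(match$pairs$treated_id, match$pairs$control_id), cohort$id)
    md <- cohort[rows, ]
    km_t <- kaplan_meier(md$obs_time_days[md$arm == "treated"],
                         md$event[md$arm == "treated"])
    km_c <- kaplan_meier(md$obs_time_days[md$arm == "control"],
                         md$event[md$arm == "control"])
    curves <- rbind(
      data.frame(arm = "treated", time = km_t$event_times, surv = km_t$survival_probs,
                 lower = km_t$lower, upper = km_t$upper, n_risk = km_t$n_risk),
      data.frame(arm = "control", time = km_c$event_times, surv = km_c$survival_probs,
                 lower = km_c$lower, upper = km_c$upper, n_risk = km_c$n_risk))
    utils::write.csv(curves, pth("survival_curves.csv"), row.names = FALSE)
    wb <- weibull_ph_fit(md$obs_time_days, md$event, arm01(md))
    lr <- log_rank_test(md$obs_time_days, md$event, md$arm)
    horizon <- build_grid(rc$horizon_years, rc$annual_discount_rate)$horizon_days
    sumry <- list(
      weibull = list(shape = wb$shape, scale = wb$scale, hr = wb$hr,
                     hr_ci_95 = as.list(wb$hr_ci_95), loglik = wb$loglik),
      log_rank = lr,
      restricted_mean_days = list(treated = restricted_mean(km_t, horizon),
                                  control = restricted_mean(km_c, horizon)),
      median_days = list(
        treated = as.list(median_survival(md$obs_time_days[md$arm == "treated"],
                                          md$event[md$arm == "treated"])),
        control = as.list(median_survival(md$obs_time_days[md$arm == "control"],
                                          md$event[md$arm == "control"]))),
      censored_fraction = list(
        treated = mean(md$event[md$arm == "treated"] == "censored"),
        control = mean(md$event[md$arm == "control"] == "censored")))
    jsonlite::write_json(sumry, pth("survival_fit.json"), auto_unbox = TRUE,
                         digits = NA)
    list(km_treated = km_t, km_control = km_c, weibull = wb, log_rank = lr,
         summary = sumry)
  })

  grid <- build_grid(rc$horizon_years, rc$annual_discount_rate)
  est <- stage("estimate", {
    e <- ipcw_cost_effectiveness(cohort, match$pairs, grid)
    jsonlite::write_json(list(
      mean_cost_by_arm = as.list(e$mean_cost_by_arm),
      mean_ly_by_arm = as.list(e$mean_ly_by_arm),
      delta_c = e$delta_c, delta_e = e$delta_e),
      pth("estimates.json"), auto_unbox = TRUE, digits = NA)
    e
  })

  cea_res <- stage("cea", {
    ce <- bootstrap_ce(cohort, match$pairs, grid, B = rc$B,
                       seed = derive_seed(rc$master_seed, 3L), wtp = rc$wtp)
    utils::write.csv(ce$draws, pth("cea_draws.csv"), row.names = FALSE)
    utils::write.csv(ce$ceac, pth("ceac.csv"), row.names = FALSE)
    jsonlite::write_json(ce_summary_list(ce), pth("summary.json"),
                         auto_unbox = TRUE, digits = NA)
    ce
  })

  sens <- NULL
  if (length(rc$scenarios)) {
    sens <- stage("sensitivity", {
      s <- run_sensitivity(cohort, match, mc, scenarios = rc$scenarios,
                           B = rc$B, seed = derive_seed(rc$master_seed, 4L),
                           wtp = rc$wtp,
                           annual_discount_rate = rc$annual_discount_rate)
      utils::write.csv(s, pth("sensitivity.csv"), row.names = FALSE)
      s
    })
  }

  stage("report", {
    writeLines(render_report(rc, cohort, match, balance, surv, est, cea_res, sens),
               pth("report.md"))
    NULL
  })

  invisible(list(out_dir = rc$out_dir, cohort = cohort, match = match,
                 balance = balance, survival = surv, estimates = est,
                 cea = cea_res, sensitivity = sens))
}

# Identity match for pre-paired estimation runs: each treated patient paired
# with the control sharing its pair_id.
self_pair_match <- function(cohort) {
  if (!"pair_id" %in% names(cohort))
    stop("run_matching = FALSE requires a pair_id column")
  tr <- cohort[cohort$arm == "treated", c("id", "pair_id")]
  ct <- cohort[cohort$arm == "control", c("id", "pair_id")]
  m <- merge(tr, ct, by = "pair_id", suffixes = c("_t", "_c"))
  pairs <- data.frame(treated_id = m$id_t, control_id = m$id_c,
                      stratum = "all", distance = NA_real_)
  structure(list(pairs = pairs,
                 treated_rows = match(pairs$treated_id, cohort$id),
                 control_rows = match(pairs$control_id, cohort$id),
                 weight_vector = NULL, n_matched = nrow(pairs),
                 n_unmatched = nrow(tr) - nrow(pairs),
                 strata_map = NULL, fitness_trace = NULL),
            class = "rw_match")
}

ce_summary_list <- function(ce) {
  list(n_pairs = ce$n_pairs, B = ce$B,
       delta_c = unname(ce$point_estimates["delta_c"]),
       delta_c_ci = as.list(ce$delta_c_ci),
       delta_e = unname(ce$point_estimates["delta_e"]),
       delta_e_ci = as.list(ce$delta_e_ci),
       inmb = lapply(ce$inmb_by_threshold, function(t)
         list(wtp = t$wtp, point = t$point, lower = unname(t$ci[1]),
              upper = unname(t$ci[2]), prob_ce = t$prob_ce)),
       quadrants = as.list(ce$quadrant_props))
}

render_report <- function(rc, cohort, match, balance, surv, est, ce, sens) {
  cfg_json <- tempfile(fileext = ".json")
  rc_hashable <- rc[setdiff(names(rc), "out_dir")]  # paths are not part of the run identity
  jsonlite::write_json(rc_hashable, cfg_json, auto_unbox = TRUE, digits = NA, force = TRUE)
  cfg_hash <- unname(tools::md5sum(cfg_json))
  unlink(cfg_json)
  q <- ce$quadrant_props
  lines <- c(
    "# Cost-effectiveness analysis report",
    "",
    sprintf("Config hash: `%s`; master seed: %d", cfg_hash, rc$master_seed),
    "",
    "## Cohort and matching",
    sprintf("- %d patients (%d treated, %.1f%%); %d matched pairs (%.1f%% of treated).",
            nrow(cohort), sum(arm01(cohort)), 100 * mean(arm01(cohort)),
            match$n_matched, 100 * match$n_matched / sum(arm01(cohort))),
    sprintf("- Post-match balance: max |SMD| %.3f; max variance ratio %.2f; %d flagged column(s).",
            max(balance$smd_matched), max(balance$variance_ratio_matched, na.rm = TRUE),
            sum(balance$flag_smd | balance$flag_variance_ratio)),
    "",
    "## Survival",
    sprintf("- Weibull hazard ratio %.3f [%.3f, %.3f]; log-rank p = %.3f.",
            surv$weibull$hr, surv$weibull$hr_ci_95[1], surv$weibull$hr_ci_95[2],
            surv$log_rank$p_value),
    sprintf("- Restricted mean survival: treated %.0f d, control %.0f d; censored %.1f%% / %.1f%%.",
            surv$summary$restricted_mean_days$treated,
            surv$summary$restricted_mean_days$control,
            100 * surv$summary$censored_fraction$treated,
            100 * surv$summary$censored_fraction$control),
    "",
    "## Cost-effectiveness (discounted)",
    sprintf("- Incremental cost $%.0f [%.0f, %.0f]; incremental LYG %.3f [%.3f, %.3f].",
            ce$point_estimates["delta_c"], ce$delta_c_ci[1], ce$delta_c_ci[2],
            ce$point_estimates["delta_e"], ce$delta_e_ci[1], ce$delta_e_ci[2]),
    vapply(ce$inmb_by_threshold, function(t)
      sprintf("- INMB at $%s/LYG: $%.0f [%.0f, %.0f]; P(cost-effective) %.1f%%.",
              format(t$wtp, big.mark = ",", scientific = FALSE), t$point, t$ci[1], t$ci[2],
              100 * t$prob_ce), character(1)),
    sprintf("- Plane quadrants: NE %.1f%%, SE %.1f%%, NW %.1f%%, SW %.1f%%.",
            100 * q["NE"], 100 * q["SE"], 100 * q["NW"], 100 * q["SW"]))
  if (!is.null(sens)) {
    lines <- c(lines, "", "## Sensitivity scenarios",
               utils::capture.output(print(sens[, c("scenario", "n_pairs", "delta_e",
                                                    "delta_c", "prob_ce_wtp1",
                                                    "prob_ce_wtp2")],
                                           row.names = FALSE)))
  }
  lines
}
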