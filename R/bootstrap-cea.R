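# Decision uncertainty via nonparametric bootstrap of the matched cohort:
# incremental net monetary benefit with bias-corrected intervals,
# cost-effectiveness acceptability curve, and plane quadrant probabilities.

#' Incremental net monetary benefit
#'
#' `INMB = wtp * delta_e - delta_c`; positive values indicate
#' cost-effectiveness at willingness-to-pay `wtp`.
#'
#' @param delta_e incremental life-years.
#' @param delta_c incremental cost.
#' @param wtp nonnegative willingness-to-pay per life-year gained.
#' @return net monetary benefit (same currency as `delta_c`).
#' @export
inmb <- function(delta_e, delta_c, wtp) {
  stopifnot(all(wtp >= 0))
  wtp * delta_e - delta_c
}

# Assemble the estimation-ready arrays for a matched (or unmatched) cohort.
ce_data <- function(cohort, pairs = NULL, grid = build_grid(),
                    cost_prefix = "cost_m", add_oop = FALSE,
                    test_cost_override = NULL) {
  J <- grid$n_intervals
  costs <- cost_matrix(cohort, J, prefix = cost_prefix)
  if (add_oop) costs <- costs + cost_matrix(cohort, J, prefix = "oop_m")
  if (!is.null(test_cost_override)) {
    cfg <- attr(cohort, "config")
    if (is.null(cfg)) stop("test_cost_override requires a cohort with a config attribute")
    tr <- arm01(cohort) == 1L
    costs[tr, 1L] <- costs[tr, 1L] - cfg$cost_model$test_cost_treated + test_cost_override
  }
  obs <- cohort$obs_time_days
  ev <- event01(cohort)
  if (is.null(pairs)) {
    ti <- which(arm01(cohort) == 1L); ci <- which(arm01(cohort) == 0L)
    paired <- FALSE
    n_pairs <- NA_integer_
  } else {
    ti <- match(pairs$treated_id, cohort$id)
    ci <- match(pairs$control_id, cohort$id)
    if (anyNA(ti) || anyNA(ci)) stop("pairs reference ids absent from the cohort")
    paired <- TRUE
    n_pairs <- nrow(pairs)
  }
  list(grid = grid, paired = paired, n_pairs = n_pairs,
       t_obs = obs[ti], t_ev = ev[ti], t_cost = costs[ti, , drop = FALSE],
       c_obs = obs[ci], c_ev = ev[ci], c_cost = costs[ci, , drop = FALSE])
}

# Estimate (delta_c, delta_e) on a pair index vector (with multiplicity).
estimate_ce <- function(dat, idx = NULL, pool_ghat = FALSE,
                        convention = "complete") {
  if (is.null(idx)) {
    ti <- seq_along(dat$t_obs); ci <- seq_along(dat$c_obs)
  } else {
    if (!dat$paired) stop("pair resampling requires paired data")
    ti <- idx; ci <- idx
  }
  ghat_t <- ghat_c <- NULL
  if (pool_ghat) {
    g <- reverse_km_censoring(c(dat$t_obs[ti], dat$c_obs[ci]),
                              c(dat$t_ev[ti], dat$c_ev[ci]))
    ghat_t <- ghat_c <- g
  }
  tot_t <- estimate_arm(dat$t_obs[ti], dat$t_ev[ti], dat$t_cost[ti, , drop = FALSE],
                        dat$grid, convention, ghat_t)
  tot_c <- estimate_arm(dat$c_obs[ci], dat$c_ev[ci], dat$c_cost[ci, , drop = FALSE],
                        dat$grid, convention, ghat_c)
  list(estimates = incremental_estimates(tot_t, tot_c),
       totals_treated = tot_t, totals_control = tot_c)
}

#' Bias-corrected bootstrap percentile interval
#'
#' BC (median-bias corrected, no acceleration) interval: with
#' `z0 = qnorm(mean(draws < point_estimate))`, the endpoints are the
#' `pnorm(2 z0 -/+ z_(alpha/2))` percentiles of the draws. When the bootstrap
#' median equals the point estimate (`z0 = 0`) this is the plain percentile
#' interval.
#'
#' @param draws bootstrap draws (length >= 100).
#' @param point_estimate point estimate on the original sample.
#' @param alpha two-sided error rate (default 0.05).
#' @return numeric vector `c(lower, upper)`.
#' @export
bc_interval <- function(draws, point_estimate, alpha = 0.05) {
  n <- length(draws)
  if (n < 100L) stop("at least 100 bootstrap draws required")
  if (max(draws) == min(draws)) {
    warning("all bootstrap draws identical; degenerate interval")
    return(c(lower = draws[1], upper = draws[1]))
  }
  frac <- mean(draws < point_estimate)
  if (frac == 0 || frac == 1) {
    warning("all draws on one side of the point estimate; bias correction clamped")
    frac <- clamp(frac, 1 / (n + 1), n / (n + 1))
  }
  z0 <- stats::qnorm(frac)
  zq <- stats::qnorm(1 - alpha / 2)
  probs <- stats::pnorm(c(2 * z0 - zq, 2 * z0 + zq))
  out <- stats::quantile(draws, probs, names = FALSE, type = 7)
  c(lower = out[1], upper = out[2])
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the proportion of bootstrap draws with
#' positive incremental net monetary benefit.
#'
#' @param draws data.frame or matrix with columns `delta_c`, `delta_e`.
#' @param wtp_grid ascending nonnegative thresholds.
#' @return data.frame with `wtp` and `probability`.
#' @export
ceac <- function(draws, wtp_grid) {
  stopifnot(all(wtp_grid >= 0), !is.unsorted(wtp_grid))
  draws <- as.data.frame(draws)
  pr <- vapply(wtp_grid, function(l) mean(inmb(draws$delta_e, draws$delta_c, l) > 0),
               numeric(1))
  data.frame(wtp = wtp_grid, probability = pr)
}

#' Cost-effectiveness plane quadrant proportions
#'
#' Quadrants of the (delta_e, delta_c) plane: NE = more effective & more
#' costly, SE = more effective & cheaper (dominant), NW = less effective &
#' more costly (dominated), SW = less effective & cheaper. Draws on an axis
#' are assigned to the positive side.
#'
#' @param draws data.frame or matrix with columns `delta_c`, `delta_e`.
#' @return named numeric vector `NE`, `NW`, `SE`, `SW` summing to 1.
#' @export
ce_plane <- function(draws) {
  draws <- as.data.frame(draws)
  if (nrow(draws) == 0L) stop("no draws")
  e_pos <- draws$delta_e >= 0
  c_pos <- draws$delta_c >= 0
  c(NE = mean(e_pos & c_pos), NW = mean(!e_pos & c_pos),
    SE = mean(e_pos & !c_pos), SW = mean(!e_pos & !c_pos))
}

#' Paired nonparametric bootstrap of the cost-effectiveness analysis
#'
#' Resamples matched pairs with replacement (preserving the 1:1 structure and
#' the within-pair cost-effect correlation) and re-runs the reverse
#' Kaplan-Meier censoring curves, IPCW weights and incremental estimates in
#' each replicate. Matching itself is not re-run inside replicates.
#'
#' @param cohort an `rw_cohort`.
#' @param pairs matched pairs data.frame (`treated_id`, `control_id`).
#' @param grid an [build_grid()] object.
#' @param B number of bootstrap replicates (>= 100; 1000 by default).
#' @param seed integer seed; the result is bit-reproducible.
#' @param wtp willingness-to-pay thresholds for INMB reporting.
#' @param ceac_grid thresholds for the acceptability curve.
#' @param pool_ghat,convention estimator options, see
#'   [ipcw_cost_effectiveness()].
#' @param cost_prefix,add_oop,test_cost_override cost accounting options, see
#'   [ipcw_cost_effectiveness()].
#' @return an object of class `rw_ce`: `draws` (B x 2), `point_estimates`,
#'   `inmb_by_threshold`, `ceac`, `quadrant_props`, `prob_ce_by_threshold`,
#'   `delta_c_ci`, `delta_e_ci`, `B`, `seed`, `n_pairs`.
#' @export
bootstrap_ce <- function(cohort, pairs, grid = build_grid(), B = 1000L,
                         seed = 1L, wtp = c(50000, 100000),
                         ceac_grid = seq(0, 200000, by = 2500),
                         pool_ghat = FALSE, convention = "complete",
                         cost_prefix = "cost_m", add_oop = FALSE,
                         test_cost_override = NULL) {
  stopifnot(B >= 100L)
  dat <- ce_data(cohort, pairs, grid, cost_prefix, add_oop, test_cost_override)
  point <- estimate_ce(dat, seq_len(dat$n_pairs), pool_ghat, convention)$estimates
  set.seed(seed)
  n <- dat$n_pairs
  draws <- matrix(NA_real_, B, 2, dimnames = list(NULL, c("delta_c", "delta_e")))
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      est <- tryCatch(
        suppressWarnings(estimate_ce(dat, idx, pool_ghat, convention)$estimates),
        error = function(e) NULL)
      if (!is.null(est)) break
      redraws <- redraws + 1L
      if (redraws > 0.05 * B) stop("more than 5% of bootstrap replicates degenerate")
    }
    draws[b, ] <- c(est$delta_c, est$delta_e)
  }
  dd <- as.data.frame(draws)
  inmb_tbl <- lapply(wtp, function(l) {
    per_draw <- inmb(dd$delta_e, dd$delta_c, l)
    pt <- inmb(point$delta_e, point$delta_c, l)
    list(wtp = l, point = pt, ci = bc_interval(per_draw, pt),
         prob_ce = mean(per_draw > 0))
  })
  names(inmb_tbl) <- paste0("wtp_", wtp)
  structure(list(
    draws = dd,
    point_estimates = c(delta_c = point$delta_c, delta_e = point$delta_e),
    estimates = point,
    delta_c_ci = bc_interval(dd$delta_c, point$delta_c),
    delta_e_ci = bc_interval(dd$delta_e, point$delta_e),
    inmb_by_threshold = inmb_tbl,
    prob_ce_by_threshold = stats::setNames(
      vapply(inmb_tbl, function(x) x$prob_ce, numeric(1)), paste0("wtp_", wtp)),
    ceac = ceac(dd, ceac_grid),
    quadrant_props = ce_plane(dd),
    B = B, seed = seed, n_pairs = n, n_redraws = redraws),
    class = "rw_ce")
}

#' @export
print.rw_ce <- function(x, ...) {
  cat(sprintf("Bootstrap cost-effectiveness result (B = %d, %d pairs)\n", x$B, x$n_pairs))
  cat(sprintf("  delta C: $%.0f [%.0f, %.0f]\n", x$point_estimates["delta_c"],
              x$delta_c_ci[1], x$delta_c_ci[2]))
  cat(sprintf("  delta E: %.3f LY [%.3f, %.3f]\n", x$point_estimates["delta_e"],
              x$delta_e_ci[1], x$delta_e_ci[2]))
  for (t in x$inmb_by_threshold)
    cat(sprintf("  INMB at $%s/LYG: $%.0f [%.0f, %.0f], P(CE) = %.1f%%\n",
                format(t$wtp, big.mark = ",", scientific = FALSE), t$point, t$ci[1], t$ci[2],
                100 * t$prob_ce))
  q <- x$quadrant_props
  cat(sprintf("  plane quadrants: NE %.1f%%, SE %.1f%%, NW %.1f%%, SW %.1f%%\n",
              100 * q["NE"], 100 * q["SE"], 100 * q["NW"], 100 * q["SW"]))
  invisible(x)
}

all_sensitivity_scenarios <- function() {
  c("base", "replacement_cap3", "no_exact_vch", "exact_plus_interior",
    "exact_plus_fraser", "reduced_test_cost", "societal", "horizon_2y",
    "horizon_1y", "egfr_positive", "egfr_negative", "sur")
}

#' Sensitivity-analysis suite
#'
#' Re-runs the cost-effectiveness analysis over a grid of scenario
#' perturbations: capped(3) replacement matching, alternative exact-matching
#' region sets, the new test priced at the old test's cost, a societal
#' perspective adding out-of-pocket drug costs, 1- and 2-year horizons, test
#' result (EGFR) subgroups stratified after matching on pairs where both
#' members carry the result, and the seemingly-unrelated-regression
#' estimator. Scenarios that change the matching specification re-run the
#' genetic search (optionally with a reduced budget via `ga_control`).
#'
#' @param cohort an `rw_cohort`.
#' @param match the base-case `rw_match`.
#' @param match_config the base-case [matching_config()].
#' @param scenarios subset of scenario names (see
#'   `all_sensitivity_scenarios()`).
#' @param B,seed bootstrap size and master seed; each scenario draws a
#'   deterministic sub-seed, so a subset of scenarios reproduces the same
#'   rows as the full suite.
#' @param wtp willingness-to-pay thresholds.
#' @param annual_discount_rate discount rate for the interval grids.
#' @param ga_control named list of [matching_config()] overrides applied when
#'   a scenario re-runs the genetic search (e.g. smaller
#'   `population_size`).
#' @param min_subgroup_pairs subgroup rows below this size are flagged, not
#'   dropped.
#' @return a data.frame with one Table-2-shaped row per scenario and an
#'   attribute `results` holding the full `rw_ce` objects.
#' @export
run_sensitivity <- function(cohort, match, match_config,
                            scenarios = all_sensitivity_scenarios(),
                            B = 1000L, seed = 1L, wtp = c(50000, 100000),
                            annual_discount_rate = 0.015,
                            ga_control = list(),
                            min_subgroup_pairs = 30L) {
  all_sc <- all_sensitivity_scenarios()
  stopifnot(all(scenarios %in% all_sc))
  grid3 <- build_grid(3, annual_discount_rate)
  rematch <- function(cfg_changes) {
    mc <- match_config
    for (nm in names(cfg_changes)) mc[[nm]] <- cfg_changes[[nm]]
    for (nm in names(ga_control)) mc[[nm]] <- ga_control[[nm]]
    genetic_search(cohort, mc)
  }
  subgroup_pairs <- function(result) {
    eg <- stats::setNames(cohort$egfr_result, cohort$id)
    p <- match$pairs
    p[eg[as.character(p$treated_id)] == result &
        eg[as.character(p$control_id)] == result, , drop = FALSE]
  }
  rows <- list(); results <- list()
  for (sc in scenarios) {
    sc_seed <- derive_seed(seed, match(sc, all_sc))
    pairs <- match$pairs
    grid <- grid3
    args <- list()
    flagged <- FALSE
    res_cor <- NA_real_
    if (sc == "replacement_cap3") {
      pairs <- rematch(list(replacement_mode = list(type = "capped", k = 3)))$pairs
    } else if (sc == "no_exact_vch") {
      pairs <- rematch(list(exact_match_names =
        setdiff(match_config$exact_match_names, "vch")))$pairs
    } else if (sc == "exact_plus_interior") {
      pairs <- rematch(list(exact_match_names =
        union(match_config$exact_match_names, "interior")))$pairs
    } else if (sc == "exact_plus_fraser") {
      pairs <- rematch(list(exact_match_names =
        union(match_config$exact_match_names, "fraser")))$pairs
    } else if (sc == "reduced_test_cost") {
      args$test_cost_override <- attr(cohort, "config")$cost_model$test_cost_control
    } else if (sc == "societal") {
      args$add_oop <- TRUE
    } else if (sc == "horizon_2y") {
      grid <- build_grid(2, annual_discount_rate)
    } else if (sc == "horizon_1y") {
      grid <- build_grid(1, annual_discount_rate)
    } else if (sc == "egfr_positive") {
      pairs <- subgroup_pairs("positive")
    } else if (sc == "egfr_negative") {
      pairs <- subgroup_pairs("negative")
    }
    if (nrow(pairs) < min_subgroup_pairs) flagged <- TRUE
    ce <- do.call(bootstrap_ce, c(list(cohort = cohort, pairs = pairs, grid = grid,
                                       B = B, seed = sc_seed, wtp = wtp), args))
    if (sc == "sur") {
      full <- do.call(estimate_ce,
                      c(list(dat = do.call(ce_data, c(list(cohort = cohort, pairs = pairs,
                                                           grid = grid), args)))))
      res_cor <- sur_estimates(full$totals_treated, full$totals_control)$residual_correlation
    }
    results[[sc]] <- ce
    t1 <- ce$inmb_by_threshold[[1]]; t2 <- ce$inmb_by_threshold[[2]]
    rows[[sc]] <- data.frame(
      scenario = sc, n_pairs = ce$n_pairs,
      delta_e = ce$point_estimates["delta_e"],
      delta_e_lower = ce$delta_e_ci[1], delta_e_upper = ce$delta_e_ci[2],
      delta_c = ce$point_estimates["delta_c"],
      delta_c_lower = ce$delta_c_ci[1], delta_c_upper = ce$delta_c_ci[2],
      inmb_wtp1 = t1$point, inmb_wtp1_lower = t1$ci[1], inmb_wtp1_upper = t1$ci[2],
      prob_ce_wtp1 = t1$prob_ce,
      inmb_wtp2 = t2$point, inmb_wtp2_lower = t2$ci[1], inmb_wtp2_upper = t2$ci[2],
      prob_ce_wtp2 = t2$prob_ce,
      residual_correlation = res_cor,
      flagged = flagged, row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
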