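test_that("the interval grid follows the discounting conventions", {
  g0 <- build_grid(3, 0)
  expect_true(all(g0$discount_factor == 1))
  g <- build_grid(3, 0.015)
  expect_equal(g$n_intervals, 36L)
  expect_equal(g$horizon_days, 1095.75)
  expect_equal(g$start_days[13], 365.25)
  expect_equal(g$discount_factor[13], 1 / 1.015)
  expect_true(all(diff(g$discount_factor) < 0))
  g1 <- build_grid(1, 0.015)
  expect_equal(g1$n_intervals, 12L)
})

test_that("IPCW weights reproduce hand-computed values on the toy dataset", {
  toy <- toy_followup()
  grid <- build_grid(3, 0)
  g <- reverse_km_censoring(toy$time, toy$event)
  W <- ipcw_weights(toy$time, toy$event, grid, g)
  L <- 365.25 / 12
  # interval 1 [0, 30.4): all four fully observed through min(death, end):
  # A, C, D die later with C >= min(T, end); B censored at 50 >= end. G = 1.
  expect_equal(unname(W[, 1]), c(1, 1, 1, 1))
  # interval 2 [30.4, 60.9): A dies at 45 (weight 1/G(45-) = 1); B censored at
  # 50 < 60.9 -> excluded; C, D survive the interval, weight 1/G(60.9-) = 1/(2/3)
  expect_equal(unname(W[, 2]), c(1, 0, 1.5, 1.5))
  # interval 3 [60.9, 91.3): A dead (1/G(45-) = 1); C dies at 70 (1/G(70-) = 1.5)
  expect_equal(unname(W[, 3]), c(1, 0, 1.5, 1.5))
  # interval 4 [91.3, 121.8): C dead-before-start keeps weight 1/G(70-) = 1.5
  expect_equal(unname(W[, 4]), c(1, 0, 1.5, 1.5))
  # with G = 0.5 past day 20, a fully observed interval carries weight 2
  g5 <- reverse_km_censoring(c(20, 100), c("censored", "death"))
  W5 <- ipcw_weights(c(20, 100), c("censored", "death"), grid, g5)
  expect_equal(surv_prob(g5, grid$start_days[2], left = TRUE), 0.5)
  expect_equal(unname(W5[, 2]), c(0, 2))
})

test_that("without censoring the estimator equals the naive mean exactly", {
  ch <- generate_cohort(no_censoring_config(n = 400, seed = 7))
  grid <- build_grid(3, 0.015)
  est <- ipcw_cost_effectiveness(ch, pairs = NULL, grid = grid)
  costs <- rwcea:::cost_matrix(ch, 36)
  ad <- rwcea:::alive_days_matrix(ch$survival_time_days, grid)
  for (a in c("treated", "control")) {
    sel <- ch$arm == a
    naive_c <- sum(grid$discount_factor * colMeans(costs[sel, ]))
    naive_e <- sum(grid$discount_factor * colMeans(ad[sel, ])) / 365.25
    expect_equal(unname(est$mean_cost_by_arm[a]), naive_c, tolerance = 1e-12)
    expect_equal(unname(est$mean_ly_by_arm[a]), naive_e, tolerance = 1e-12)
  }
  expect_true(all(est$weights_summary == 1))
})

test_that("weighted totals handle constant-cost and boundary-death toys", {
  L <- 365.25 / 12
  grid <- build_grid(3, 0)
  # one patient alive through all 36 intervals at constant cost c
  ch1 <- manual_cohort(36.5 * L, "censored", "treated", monthly_cost = 500)
  tot <- rwcea:::estimate_arm(ch1$obs_time_days, ch1$event,
                              rwcea:::cost_matrix(ch1, 36), grid)
  expect_equal(tot$mean_cost, 36 * 500, tolerance = 1e-9)
  expect_equal(tot$mean_ly, 3, tolerance = 1e-9)
  # death exactly at the end of interval 12 -> one discounted life-year at r=0
  ch2 <- manual_cohort(12 * L, "death", "treated", monthly_cost = 1000)
  tot2 <- rwcea:::estimate_arm(ch2$obs_time_days, ch2$event,
                               rwcea:::cost_matrix(ch2, 36), grid)
  expect_equal(tot2$mean_ly, 1, tolerance = 1e-9)
  expect_equal(tot2$mean_cost, 12000, tolerance = 1e-9)
})

test_that("identical arms give zero increments and the regression path agrees", {
  ch <- generate_cohort(quick_config(n = 600, seed = 11))
  sel <- which(ch$arm == "treated")
  pairs <- data.frame(treated_id = ch$id[sel], control_id = ch$id[sel])
  # pairing the treated arm against itself: deltas identically zero
  est <- ipcw_cost_effectiveness(ch, pairs)
  expect_equal(est$delta_c, 0, tolerance = 1e-10)
  expect_equal(est$delta_e, 0, tolerance = 1e-10)
  # regression route stored alongside the difference of means
  est2 <- ipcw_cost_effectiveness(ch, pairs = NULL)
  expect_equal(est2$delta_c, est2$delta_c_regression, tolerance = 1e-10)
  expect_equal(est2$delta_e, est2$delta_e_regression, tolerance = 1e-10)
})

test_that("discounted totals are monotone non-increasing in the discount rate", {
  ch <- generate_cohort(quick_config(n = 500, seed = 13))
  vals <- vapply(c(0, 0.015, 0.05, 0.1), function(r) {
    est <- ipcw_cost_effectiveness(ch, pairs = NULL, grid = build_grid(3, r))
    unname(est$mean_cost_by_arm["control"])
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("horizon nesting: 1-year estimates equal 3-year with later costs zeroed", {
  ch <- generate_cohort(quick_config(n = 500, seed = 17))
  est1 <- ipcw_cost_effectiveness(ch, pairs = NULL, grid = build_grid(1, 0.015))
  ch0 <- ch
  for (m in 13:36) ch0[[sprintf("cost_m%02d", m)]] <- 0
  est3 <- ipcw_cost_effectiveness(ch0, pairs = NULL, grid = build_grid(3, 0.015))
  expect_equal(est1$mean_cost_by_arm, est3$mean_cost_by_arm, tolerance = 1e-10)
})

test_that("per-arm censoring curves differ from pooled estimation as configured", {
  ch <- generate_cohort(quick_config(n = 800, seed = 19))
  sep <- ipcw_cost_effectiveness(ch, pairs = NULL, pool_ghat = FALSE)
  pool <- ipcw_cost_effectiveness(ch, pairs = NULL, pool_ghat = TRUE)
  expect_false(identical(sep$delta_c, pool$delta_c))
  expect_false(identical(sep$delta_e, pool$delta_e))
})

test_that("SUR equals least squares with identical regressors and recovers rho", {
  mk_totals <- function(n, rho, base_c = 50000, base_e = 1.2) {
    z <- matrix(rnorm(2 * n), n, 2)
    eC <- z[, 1]
    eE <- rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]
    structure(list(mean_cost = base_c + mean(eC) * 1000,
                   mean_ly = base_e + mean(eE) * 0.1,
                   y_cost = base_c + 1000 * eC, y_ly = base_e + 0.1 * eE),
              class = "rw_arm_totals")
  }
  set.seed(23)
  for (rho in c(0, 0.5)) {
    tt <- mk_totals(4000, rho, base_c = 53000, base_e = 1.28)
    tc <- mk_totals(4000, rho)
    s <- sur_estimates(tt, tc)
    expect_equal(s$delta_c, tt$mean_cost - tc$mean_cost, tolerance = 1e-9)
    expect_equal(s$delta_e, tt$mean_ly - tc$mean_ly, tolerance = 1e-9)
    expect_equal(s$residual_correlation, rho, tolerance = 0.05)
  }
  # on real cohort data the SUR point estimates equal the partitioned path
  ch <- generate_cohort(quick_config(n = 400, seed = 29))
  dat <- rwcea:::ce_data(ch, NULL, build_grid())
  full <- rwcea:::estimate_ce(dat)
  s2 <- sur_estimates(full$totals_treated, full$totals_control)
  expect_equal(s2$delta_c, full$estimates$delta_c, tolerance = 1e-9)
  expect_equal(s2$delta_e, full$estimates$delta_e, tolerance = 1e-9)
})
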