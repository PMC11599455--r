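test_that("net monetary benefit arithmetic", {
  expect_equal(inmb(0, 0, 50000), 0)
  expect_equal(inmb(0.1, 5000, 50000), 0)
  expect_equal(inmb(0.08, 3529, 100000), 4471)
  expect_equal(inmb(c(0.1, 0.2), c(1000, 2000), 50000), c(4000, 8000))
  expect_error(inmb(0.1, 100, -5))
})

test_that("bias-corrected intervals reduce to percentile intervals at z0 = 0", {
  draws <- 1:1000
  bc <- bc_interval(draws, 500.5)  # median equals the point estimate
  pct <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_equal(unname(bc), pct)
  expect_equal(unname(bc[1]), 26, tolerance = 1)
  expect_equal(unname(bc[2]), 975, tolerance = 1)
  expect_error(bc_interval(1:50, 25), "100")
  expect_warning(b2 <- bc_interval(rep(3, 200), 3), "identical")
  expect_equal(unname(b2), c(3, 3))
  expect_warning(bc_interval(1:200, 500), "one side")
})

test_that("bias correction shifts the interval toward the long tail", {
  set.seed(3)
  draws <- exp(rnorm(2000))
  point <- mean(draws)  # above the median of a lognormal: z0 > 0
  bc <- bc_interval(draws, point)
  pct <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_gt(bc[1], pct[1])
  expect_gt(bc[2], pct[2])
})

test_that("acceptability curve identities hold", {
  draws <- data.frame(delta_c = c(-1000, 500, 2000, 3000),
                      delta_e = c(0.05, 0.02, 0.04, 0.06))
  cc <- ceac(draws, c(0, 25000, 50000, 1e6))
  expect_equal(cc$probability[1], mean(draws$delta_c < 0))
  # all draws with positive dE and dC: nondecreasing with limit 1
  expect_true(all(diff(ceac(draws[draws$delta_c > 0, ],
                            seq(0, 2e5, 5000))$probability) >= 0))
  expect_equal(cc$probability[length(cc$wtp)], 1)
  # each draw switches on exactly at lambda = dC/dE
  pos <- draws[draws$delta_c > 0, ]
  switch_pts <- pos$delta_c / pos$delta_e
  lam <- sort(c(switch_pts - 1, switch_pts + 1))
  pr <- ceac(pos, lam)$probability
  expect_equal(pr, vapply(lam, function(l) mean(switch_pts < l), numeric(1)))
})

test_that("plane quadrants count correctly and sum to one", {
  expect_equal(ce_plane(data.frame(delta_c = c(1, 2), delta_e = c(1, 2))),
               c(NE = 1, NW = 0, SE = 0, SW = 0))
  four <- data.frame(delta_c = c(1, 1, -1, -1), delta_e = c(1, -1, 1, -1))
  expect_equal(unname(ce_plane(four)), rep(0.25, 4))
  # boundary draws go to the positive side
  expect_equal(ce_plane(data.frame(delta_c = 0, delta_e = 0)),
               c(NE = 1, NW = 0, SE = 0, SW = 0))
  set.seed(7)
  rnd <- data.frame(delta_c = rnorm(231), delta_e = rnorm(231))
  q <- ce_plane(rnd)
  expect_equal(sum(q), 1)
  expect_true(all(abs(q * 231 - round(q * 231)) < 1e-9))
})

test_that("paired bootstrap is deterministic and internally consistent", {
  ch <- generate_cohort(quick_config(n = 500, seed = 3))
  mc <- quick_matching_config(ch, max_generations = 0L)
  m <- genetic_search(ch, mc)
  ce <- bootstrap_ce(ch, m$pairs, B = 120, seed = 11)
  ce2 <- bootstrap_ce(ch, m$pairs, B = 120, seed = 11)
  expect_identical(ce$draws, ce2$draws)
  expect_identical(ce$ceac, ce2$ceac)
  # prob_ce at the reporting thresholds equals the CEAC at those grid points
  for (t in ce$inmb_by_threshold) {
    expect_equal(t$prob_ce, ce$ceac$probability[ce$ceac$wtp == t$wtp])
    expect_equal(t$point, inmb(ce$point_estimates["delta_e"],
                               ce$point_estimates["delta_c"], t$wtp),
                 ignore_attr = TRUE, tolerance = 1e-12)
    # the INMB interval is the BC interval of the per-draw INMBs
    per_draw <- inmb(ce$draws$delta_e, ce$draws$delta_c, t$wtp)
    expect_equal(t$ci, bc_interval(per_draw, t$point))
  }
  expect_equal(sum(ce$quadrant_props), 1)
  expect_true(all(abs(ce$quadrant_props * ce$B -
                        round(ce$quadrant_props * ce$B)) < 1e-9))
})

test_that("a null construction centers the draws near zero", {
  # no treatment effect anywhere: random pairing of exchangeable arms
  ch <- generate_cohort(symmetric_config(
    n = 700, seed = 13,
    assignment_coefficients = c(age = 0), survival_coefficients = c(age = 0)))
  set.seed(5)
  t_ids <- ch$id[ch$arm == "treated"]
  c_ids <- sample(ch$id[ch$arm == "control"], length(t_ids))
  ce <- bootstrap_ce(ch, data.frame(treated_id = t_ids, control_id = c_ids),
                     B = 200, seed = 17)
  p50 <- ce$prob_ce_by_threshold[["wtp_50000"]]
  expect_gt(p50, 0.05)
  expect_lt(p50, 0.95)
  # the point estimates are sampling noise around zero: within 3 bootstrap SDs
  expect_lt(abs(ce$point_estimates["delta_e"]), 3 * sd(ce$draws$delta_e))
  expect_lt(abs(ce$point_estimates["delta_c"]), 3 * sd(ce$draws$delta_c))
})

test_that("the sensitivity suite reproduces the base run and accounts test costs", {
  ch <- generate_cohort(quick_config(n = 600, seed = 19))
  mc <- quick_matching_config(ch, max_generations = 0L)
  m <- genetic_search(ch, mc)
  suite <- run_sensitivity(ch, m, mc,
                           scenarios = c("base", "reduced_test_cost",
                                         "horizon_1y", "egfr_negative", "sur"),
                           B = 100, seed = 23)
  base_row <- suite[suite$scenario == "base", ]
  standalone <- bootstrap_ce(ch, m$pairs, B = 100,
                             seed = derive_seed(23, 1L))
  expect_equal(base_row$delta_c, unname(standalone$point_estimates["delta_c"]))
  expect_equal(base_row$inmb_wtp1_lower,
               unname(standalone$inmb_by_threshold[[1]]$ci[1]))
  # pricing the new test at the old test's cost shifts delta C by exactly the
  # undiscounted month-1 difference (weights are unchanged)
  red <- suite[suite$scenario == "reduced_test_cost", ]
  expect_equal(base_row$delta_c - red$delta_c, 1200 - 228, tolerance = 1e-8)
  expect_equal(red$delta_e, base_row$delta_e, tolerance = 1e-10)
  # 1-year horizon shrinks the incremental life-years
  h1 <- suite[suite$scenario == "horizon_1y", ]
  expect_lt(abs(h1$delta_e), max(abs(base_row$delta_e), 0.05) + 1e-9)
  # subgroup rows use pair subsets where both members carry the result
  neg <- suite[suite$scenario == "egfr_negative", ]
  eg <- stats::setNames(ch$egfr_result, ch$id)
  np <- sum(eg[as.character(m$pairs$treated_id)] == "negative" &
              eg[as.character(m$pairs$control_id)] == "negative")
  expect_equal(neg$n_pairs, np)
  # SUR row carries a finite residual correlation and matches the base deltas
  sur <- suite[suite$scenario == "sur", ]
  expect_true(is.finite(sur$residual_correlation))
  expect_equal(sur$delta_c, base_row$delta_c, tolerance = 1e-9)
})
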