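test_that("null-model propensity scores equal the treated fraction", {
  ch <- generate_cohort(cohort_config(
    n_patients = 4000, seed = 3,
    assignment_coefficients = c(age = 0, sex_male = 0)))
  ps <- estimate_propensity(ch, c("age", "sex_male"))
  expect_lt(diff(range(ps$pscore)), 0.1)
  expect_equal(mean(ps$pscore), mean(ch$arm == "treated"), tolerance = 1e-6)
})

test_that("logistic fit recovers the closed-form 2x2 log-odds", {
  # treated: 40 with x=1, 10 with x=0; control: 10 with x=1, 40 with x=0
  df <- data.frame(id = 1:100,
                   arm = rep(c("treated", "control"), each = 50),
                   x = c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40)))
  ps <- estimate_propensity(df, "x")
  expect_equal(unname(ps$coefficients["x"]), log(16), tolerance = 1e-6)
})

test_that("a perfectly separating covariate is clipped with a warning", {
  df <- data.frame(id = 1:60, arm = rep(c("treated", "control"), each = 30),
                   x = rep(c(1, 0), each = 30))
  expect_warning(ps <- estimate_propensity(df, "x"), "separation")
  expect_true(all(ps$pscore >= 1e-6 & ps$pscore <= 1 - 1e-6))
})

test_that("generalized distance reduces to Euclidean and obeys identities", {
  M <- diag(2)  # identity covariance
  x <- c(1, 2); y <- c(4, 6)
  expect_equal(generalized_distance(x, y, M, c(1, 1)), 5)
  expect_equal(generalized_distance(x, x, M, c(2, 3)), 0)
  # toy covariance: brute-force quadratic form oracle
  S <- matrix(c(2, 0.5, 0.5, 1), 2)
  Minv <- chol_inv <- rwcea:::chol_inv_factor(S)
  d <- generalized_distance(x, y, Minv, c(1, 1))
  expect_equal(d^2, drop(t(x - y) %*% solve(S) %*% (x - y)), tolerance = 1e-12)
  # weighted case against direct arithmetic
  w <- c(0.5, 4)
  d2 <- generalized_distance(x, y, Minv, w)^2
  z <- Minv %*% (x - y)
  expect_equal(d2, sum(w * z^2), tolerance = 1e-12)
  # symmetry
  expect_equal(generalized_distance(y, x, Minv, w),
               generalized_distance(x, y, Minv, w))
})

test_that("greedy matching honours strata, exhaustion and replacement caps", {
  ch <- generate_cohort(quick_config(n = 400, seed = 7))
  mc <- quick_matching_config(ch)
  m <- match_with_weights(ch, rep(1, 11), mc)
  # paired patients share exact-match covariate values
  for (nm in mc$exact_match_names) {
    v <- stats::setNames(as.character(ch[[nm]]), ch$id)
    expect_identical(unname(v[as.character(m$pairs$treated_id)]),
                     unname(v[as.character(m$pairs$control_id)]))
  }
  # without replacement: controls unique, treated unique
  expect_false(any(duplicated(m$pairs$control_id)))
  expect_false(any(duplicated(m$pairs$treated_id)))
  # capped(k): no control used more than k times
  mc3 <- quick_matching_config(ch, replacement_mode = list(type = "capped", k = 3))
  m3 <- match_with_weights(ch, rep(1, 11), mc3)
  expect_lte(max(table(m3$pairs$control_id)), 3)
  expect_gte(m3$n_matched, m$n_matched)
})

test_that("identical twins match at distance zero; scarcity limits matches", {
  # cohort of exact duplicates: every treated has an identical control
  base <- data.frame(id = 1:20, x = rnorm(20), g = rep(c("a", "b"), 10))
  df <- rbind(transform(base, arm = "treated"),
              transform(base, id = id + 100, arm = "control"))
  mc <- matching_config(covariate_names = c("x", "g"), exact_match_names = "g",
                        include_propensity = FALSE, seed = 5)
  m <- match_with_weights(df, rep(1, 2), mc)
  expect_equal(m$n_matched, 20)
  expect_true(all(m$pairs$distance < 1e-8))
  # 2 treated, 1 control, no replacement -> 1 match
  df2 <- data.frame(id = 1:3, arm = c("treated", "treated", "control"),
                    x = c(0, 1, 0.5), g = "a")
  m2 <- match_with_weights(df2, 1, matching_config(
    covariate_names = "x", exact_match_names = character(0),
    include_propensity = FALSE, seed = 1))
  expect_equal(m2$n_matched, 1)
  # capped(3): 4 treated nearest to the single control -> used exactly 3 times
  df3 <- data.frame(id = 1:5, arm = c(rep("treated", 4), "control"),
                    x = c(0.1, 0.2, 0.3, 0.4, 0.25), g = "a")
  m3 <- match_with_weights(df3, 1, matching_config(
    covariate_names = "x", exact_match_names = character(0),
    include_propensity = FALSE,
    replacement_mode = list(type = "capped", k = 3), seed = 1))
  expect_equal(m3$n_matched, 3)
  expect_equal(unname(table(m3$pairs$control_id)[["5"]]), 3)
})

test_that("balance fitness is 1 for perfect matches and detects large shifts", {
  base <- data.frame(id = 1:60, x = rnorm(60), b = rbinom(60, 1, 0.4), g = "a")
  df <- rbind(transform(base, arm = "treated"),
              transform(base, id = id + 100, arm = "control"))
  mc <- matching_config(covariate_names = c("x", "b"),
                        exact_match_names = character(0),
                        include_propensity = FALSE, ks_boot_reps = 80, seed = 3)
  m <- match_with_weights(df, rep(1, 2), mc)
  f <- balance_fitness(m, df, mc)
  expect_true(all(f == 1))
  # one covariate shifted by 3 SD between matched arms -> tiny minimum p
  set.seed(9)
  df_shift <- df
  df_shift$x[df_shift$arm == "treated"] <-
    df_shift$x[df_shift$arm == "treated"] + 3
  # force pairing by id so the shift survives matching
  m2 <- m
  f2 <- balance_fitness(m2, df_shift, mc)
  expect_lt(min(f2), 0.001)
})

test_that("doubling the KS bootstrap replicates leaves the statistic unchanged", {
  set.seed(11)
  x <- rnorm(150); y <- rnorm(150, 0.25)
  expect_identical(rwcea:::ks_statistic(x, y), rwcea:::ks_statistic(x, y))
  expect_equal(rwcea:::ks_statistic(x, y),
               unname(suppressWarnings(stats::ks.test(x, y)$statistic)))
  set.seed(12); p1 <- rwcea:::ks_boot_p(x, y, 300)
  set.seed(13); p2 <- rwcea:::ks_boot_p(x, y, 600)
  expect_lt(abs(p1 - p2), 4 * sqrt(0.25 / 300) + 0.02)
})

test_that("lexical comparison is decided by the first differing element", {
  expect_equal(lexical_compare(c(0.01, 0.9), c(0.02, 0.1)), "b_better")
  expect_equal(lexical_compare(c(0.05, 0.3), c(0.05, 0.3)), "tie")
  expect_equal(lexical_compare(c(0.05, 0.2, 0.9), c(0.05, 0.3, 0.1)), "b_better")
  expect_equal(lexical_compare(c(0.6, 0.7), c(0.5, 0.9)), "a_better")
})

test_that("zero-generation search reproduces plain Mahalanobis matching", {
  ch <- generate_cohort(quick_config(n = 300, seed = 19))
  mc <- quick_matching_config(ch, max_generations = 0L)
  gs <- genetic_search(ch, mc)
  m <- match_with_weights(ch, rep(1, 11), mc)
  expect_identical(gs$pairs, m$pairs)
  expect_error(genetic_search(ch, quick_matching_config(ch, population_size = 4L)),
               "population_size")
})

test_that("genetic search improves balance, is elitist and reproducible", {
  ch <- generate_cohort(quick_config(n = 500, seed = 21))
  mc <- quick_matching_config(ch, population_size = 10L, max_generations = 4L,
                              ks_boot_reps = 60L)
  gs <- genetic_search(ch, mc)
  # elitism: best fitness lexically nondecreasing across generations
  for (g in seq_along(gs$fitness_trace)[-1]) {
    expect_false(lexical_compare(gs$fitness_trace[[g]],
                                 gs$fitness_trace[[g - 1]]) == "b_better")
  }
  # balance improvement on the assignment-driving covariate
  b <- balance_report(ch, gs, mc)
  vch_row <- b[b$covariate == "vch", ]
  expect_lt(vch_row$smd_matched, vch_row$smd_unmatched)
  expect_identical(vch_row$smd_matched, 0)  # exact-match covariate
  # reproducibility
  gs2 <- genetic_search(ch, mc)
  expect_identical(gs$pairs, gs2$pairs)
  expect_identical(gs$weight_vector, gs2$weight_vector)
})
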