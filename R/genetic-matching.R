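# 1:1 genetic matching: covariate weights for a generalized Mahalanobis
# distance are evolved to lexically maximize the sorted vector of post-match
# balance p-values (bootstrapped Kolmogorov-Smirnov for continuous covariates,
# paired t for binaries), within exact-matching strata.

#' Configuration for genetic matching
#'
#' @param covariate_names covariates entering the distance and the balance
#'   fitness.
#' @param exact_match_names subset of `covariate_names` whose values must be
#'   identical within a matched pair (stratum matching).
#' @param include_propensity append the logistic propensity score as an extra
#'   matching covariate (its fitted coefficients also scale the initial
#'   search jitter).
#' @param replacement_mode `"none"` (each control used at most once) or
#'   `list(type = "capped", k = 3)` allowing each control up to k uses.
#' @param population_size,max_generations,stall_generations genetic search
#'   budget; the search stops after `stall_generations` without lexical
#'   improvement. `max_generations = 0` returns the match under all-ones
#'   weights (plain Mahalanobis matching).
#' @param ks_boot_reps bootstrap resamples for the Kolmogorov-Smirnov balance
#'   p-values.
#' @param weight_bounds positive lower/upper bounds for covariate weights.
#' @param poly_terms add squared-age and age-by-sex balance terms to the
#'   fitness when `age`/`sex_male` are among the covariates.
#' @param mutation_rate,mutation_sd per-gene probability and log-scale SD of
#'   multiplicative lognormal mutation.
#' @param seed integer seed for the randomized matching order, tie-breaking
#'   and evolution.
#' @return an object of class `rw_matching_config`.
#' @export
matching_config <- function(covariate_names,
                            exact_match_names = character(0),
                            include_propensity = TRUE,
                            replacement_mode = "none",
                            population_size = 100L,
                            max_generations = 30L,
                            stall_generations = 8L,
                            ks_boot_reps = 300L,
                            weight_bounds = c(1e-3, 1e3),
                            poly_terms = TRUE,
                            mutation_rate = 0.25,
                            mutation_sd = 0.4,
                            seed = 1L) {
  if (is.character(replacement_mode)) replacement_mode <- list(type = replacement_mode)
  stopifnot(all(exact_match_names %in% covariate_names),
            weight_bounds[1] > 0, weight_bounds[2] > weight_bounds[1],
            replacement_mode$type %in% c("none", "capped"))
  if (identical(replacement_mode$type, "capped"))
    stopifnot(replacement_mode$k >= 1)
  structure(list(covariate_names = covariate_names,
                 exact_match_names = exact_match_names,
                 include_propensity = include_propensity,
                 replacement_mode = replacement_mode,
                 population_size = as.integer(population_size),
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 ks_boot_reps = as.integer(ks_boot_reps),
                 weight_bounds = weight_bounds,
                 poly_terms = isTRUE(poly_terms),
                 mutation_rate = mutation_rate,
                 mutation_sd = mutation_sd,
                 seed = as.integer(seed)),
            class = "rw_matching_config")
}

#' Logistic propensity score
#'
#' Fitted probability of treatment given the one-hot expanded covariates.
#' Near-separation (fitted probabilities numerically 0 or 1) triggers a
#' warning and the probabilities are clipped to \[1e-6, 1 - 1e-6\].
#'
#' @param cohort an `rw_cohort` (or data.frame with an `arm` column).
#' @param covariate_names covariates for the linear predictor.
#' @return list with `pscore` (per-patient probability) and `coefficients`
#'   (standardized, excluding intercept).
#' @export
estimate_propensity <- function(cohort, covariate_names) {
  y <- arm01(cohort)
  if (length(unique(y)) < 2L) stop("both arms must be nonempty")
  X <- one_hot_matrix(cohort, covariate_names)
  fit <- suppressWarnings(
    stats::glm.fit(cbind(`(Intercept)` = 1, X), y, family = stats::binomial()))
  p <- fit$fitted.values
  eps <- 1e-6
  if (any(p < 1e-8 | p > 1 - 1e-8)) {
    warning("near-separation in the propensity model; probabilities clipped")
    p <- clamp(p, eps, 1 - eps)
  }
  beta <- fit$coefficients[-1L]
  beta[is.na(beta)] <- 0
  sds <- apply(X, 2, stats::sd)
  list(pscore = p, coefficients = beta, std_coefficients = beta * sds)
}

# Inverse Cholesky factor M with M' M = S^-1 (so z = M x whitens x); a small
# ridge is added if S is not positive definite.
chol_inv_factor <- function(S) {
  U <- tryCatch(chol(S), error = function(e) {
    warning("singular covariance; adding ridge 1e-8 * I")
    chol(S + diag(1e-8, nrow(S)))
  })
  t(solve(U))
}

#' Generalized weighted Mahalanobis distance between two covariate vectors
#'
#' `d = sqrt((x_i - x_j)' M' diag(w) M (x_i - x_j))` where `M` is the inverse
#' Cholesky factor of the pooled pre-match covariate covariance. With unit
#' weights and identity covariance this reduces to Euclidean distance.
#'
#' @param x_i,x_j covariate vectors (including the propensity score if
#'   configured).
#' @param chol_inv inverse Cholesky factor from [chol_inv_factor()].
#' @param w strictly positive covariate weights.
#' @return a nonnegative scalar.
#' @export
generalized_distance <- function(x_i, x_j, chol_inv, w) {
  stopifnot(all(w > 0), length(x_i) == length(x_j))
  z <- chol_inv %*% (x_i - x_j)
  sqrt(sum(w * z^2))
}

# Precompute everything weight-independent: whitened covariates, strata,
# fitness columns, propensity.
match_prep <- function(cohort, config) {
  X <- one_hot_matrix(cohort, config$covariate_names)
  ps <- NULL
  if (config$include_propensity) {
    ps <- estimate_propensity(cohort, config$covariate_names)
    X <- cbind(X, pscore = ps$pscore)
  }
  S <- stats::cov(X)
  M <- chol_inv_factor(S)
  Z <- X %*% t(M)
  colnames(Z) <- colnames(X)
  # exact-matching strata on the raw covariate values
  if (length(config$exact_match_names)) {
    key <- do.call(paste, c(lapply(config$exact_match_names,
                                   function(nm) as.character(cohort[[nm]])), sep = "|"))
  } else key <- rep("all", nrow(cohort))
  # balance-fitness columns: one-hot covariates plus polynomial/interaction terms
  Fm <- one_hot_matrix(cohort, config$covariate_names)
  if (config$poly_terms && "age" %in% colnames(Fm)) {
    Fm <- cbind(Fm, age_sq = Fm[, "age"]^2)
    if ("sex_male" %in% colnames(Fm))
      Fm <- cbind(Fm, age_x_sex = Fm[, "age"] * Fm[, "sex_male"])
  }
  is_cont <- apply(Fm, 2, function(x) length(unique(x)) > 2L)
  trt <- which(arm01(cohort) == 1L)
  ctl <- which(arm01(cohort) == 0L)
  controls_by_stratum <- split(ctl, key[ctl])
  list(cohort = cohort, X = X, Z = Z, M = M, key = key,
       fitness = Fm, is_cont = is_cont,
       treated = trt, controls_by_stratum = controls_by_stratum,
       propensity = ps, n_weights = ncol(X))
}

# Greedy nearest-neighbour matching within strata for one weight vector.
# Uses the caller's RNG stream for order and tie-breaks.
match_with_weights_prep <- function(prep, w, config) {
  Zw <- sweep(prep$Z, 2, sqrt(w), "*")
  cap <- if (identical(config$replacement_mode$type, "capped"))
    config$replacement_mode$k else 1L
  use_count <- integer(nrow(prep$Z))
  order_t <- prep$treated[sample.int(length(prep$treated))]
  t_id <- integer(0); c_id <- integer(0); dist <- numeric(0)
  for (t in order_t) {
    cands <- prep$controls_by_stratum[[prep$key[t]]]
    if (is.null(cands)) next
    cands <- cands[use_count[cands] < cap]
    if (!length(cands)) next
    diff <- Zw[cands, , drop = FALSE] -
      matrix(Zw[t, ], nrow = length(cands), ncol = ncol(Zw), byrow = TRUE)
    d2 <- rowSums(diff * diff)
    m <- min(d2)
    tied <- which(d2 <= m + 1e-12)
    pick <- if (length(tied) > 1L) tied[sample.int(length(tied), 1L)] else tied
    ctl <- cands[pick]
    use_count[ctl] <- use_count[ctl] + 1L
    t_id <- c(t_id, t); c_id <- c(c_id, ctl); dist <- c(dist, sqrt(max(m, 0)))
  }
  ids <- prep$cohort$id
  pairs <- data.frame(treated_id = ids[t_id], control_id = ids[c_id],
                      stratum = prep$key[t_id], distance = dist,
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs,
                 treated_rows = t_id, control_rows = c_id,
                 weight_vector = stats::setNames(w, colnames(prep$Z)),
                 n_matched = nrow(pairs),
                 n_unmatched = length(prep$treated) - nrow(pairs),
                 strata_map = stats::setNames(prep$key, ids),
                 fitness_trace = NULL),
            class = "rw_match")
}

#' Match treated to control patients under a fixed weight vector
#'
#' Greedy nearest-neighbour matching on the generalized weighted Mahalanobis
#' distance within exact-matching strata, in a seeded random treated order
#' with seeded random tie-breaking. Without replacement each control is used
#' at most once; with `capped(k)` replacement at most k times. Treated
#' patients with no available in-stratum control remain unmatched.
#'
#' @param cohort an `rw_cohort`.
#' @param w strictly positive weight vector over the matching columns
#'   (one-hot covariates plus the propensity score if configured).
#' @param config an [matching_config()] object.
#' @return an object of class `rw_match` with elements `pairs` (data.frame
#'   `treated_id`, `control_id`, `stratum`, `distance`), `weight_vector`,
#'   `n_matched`, `strata_map`.
#' @export
match_with_weights <- function(cohort, w, config) {
  prep <- match_prep(cohort, config)
  stopifnot(length(w) == prep$n_weights, all(w > 0))
  set.seed(config$seed)
  match_with_weights_prep(prep, w, config)
}

# Sorted ascending p-value vector of post-match balance.
balance_fitness_prep <- function(match, prep, config) {
  ti <- match$treated_rows
  ci <- match$control_rows
  if (length(ti) < 10L) stop("fewer than 10 matched pairs; balance fitness undefined")
  Fm <- prep$fitness
  p <- unlist(lapply(seq_len(ncol(Fm)), function(k) {
    if (prep$is_cont[k])
      c(ks_boot_p(Fm[ti, k], Fm[ci, k], config$ks_boot_reps),
        paired_t_p(Fm[ti, k], Fm[ci, k]))
    else paired_t_p(Fm[ti, k], Fm[ci, k])
  }))
  sort(p)
}

#' Post-match balance fitness: sorted p-value vector
#'
#' For each continuous balance column, both a bootstrapped
#' Kolmogorov-Smirnov p-value (sensitive to any distributional difference)
#' and a paired t-test p-value (sensitive to mean shifts the KS test cannot
#' resolve at moderate n) of the matched treated versus control values; for
#' each binary column a paired t-test p-value over pair differences;
#' returned sorted ascending (worst-balanced first). A column constant in
#' both arms scores p = 1.
#'
#' @param match an `rw_match`.
#' @param cohort the cohort the match was computed on.
#' @param config the [matching_config()] used.
#' @return numeric vector of sorted p-values.
#' @export
balance_fitness <- function(match, cohort, config) {
  prep <- match_prep(cohort, config)
  m <- match
  if (is.null(m$treated_rows)) {
    m$treated_rows <- match(match$pairs$treated_id, cohort$id)
    m$control_rows <- match(match$pairs$control_id, cohort$id)
  }
  balance_fitness_prep(m, prep, config)
}

#' Lexical comparison of sorted p-value vectors
#'
#' Compares element-wise from the smallest (worst) p-value; at the first
#' index where the vectors differ, the larger p-value wins.
#'
#' @param p_a,p_b sorted ascending p-value vectors of equal length.
#' @return `"a_better"`, `"b_better"` or `"tie"`.
#' @export
lexical_compare <- function(p_a, p_b) {
  stopifnot(length(p_a) == length(p_b))
  for (k in seq_along(p_a)) {
    if (p_a[k] > p_b[k]) return("a_better")
    if (p_b[k] > p_a[k]) return("b_better")
  }
  "tie"
}

# Rank a population of fitness vectors best-first, consistent with
# lexical_compare.
lexical_order <- function(P) {
  do.call(order, c(lapply(seq_len(ncol(P)), function(j) P[, j]),
                   list(decreasing = TRUE)))
}

#' Genetic search for balance-optimal matching weights
#'
#' Evolves a population of covariate weight vectors: each candidate induces a
#' greedy nearest-neighbour match whose balance fitness (sorted bootstrapped
#' KS / paired-t p-values) is ranked lexically; tournament selection, blend
#' crossover, multiplicative lognormal mutation and single-individual elitism
#' produce the next generation. The population is initialized around
#' all-ones weights with jitter scaled by the standardized propensity
#' coefficients. The search stops at `max_generations` or after
#' `stall_generations` without lexical improvement and returns the match of
#' the best-ever weight vector; fully reproducible under the config seed.
#'
#' @param cohort an `rw_cohort`.
#' @param config an [matching_config()] object.
#' @return an `rw_match` with `weight_vector`, `fitness_trace` (per
#'   generation, the best sorted p-value vector) and `best_fitness`.
#' @export
genetic_search <- function(cohort, config) {
  if (config$population_size < 8L) stop("population_size must be at least 8")
  set.seed(config$seed)
  prep <- match_prep(cohort, config)
  p <- prep$n_weights
  ones <- rep(1, p)
  if (config$max_generations == 0L) {
    m <- match_with_weights_prep(prep, ones, config)
    m$fitness_trace <- list()
    m$best_fitness <- balance_fitness_prep(m, prep, config)
    return(m)
  }
  lo <- config$weight_bounds[1]; hi <- config$weight_bounds[2]
  jit <- rep(1, p)
  if (!is.null(prep$propensity)) {
    sc <- abs(prep$propensity$std_coefficients)
    jit[seq_along(sc)] <- 1 + sc / max(max(sc), 1e-8)
  }
  pop <- matrix(1, config$population_size, p)
  for (i in 2:config$population_size)
    pop[i, ] <- clamp(exp(stats::rnorm(p, 0, 0.35 * jit)), lo, hi)

  evaluate <- function(w) {
    m <- match_with_weights_prep(prep, w, config)
    list(match = m, fit = balance_fitness_prep(m, prep, config))
  }
  evals <- apply(pop, 1, evaluate)
  P <- t(vapply(evals, `[[`, numeric(length(evals[[1]]$fit)), "fit"))
  best_idx <- lexical_order(P)[1]
  best <- list(w = pop[best_idx, ], fit = P[best_idx, ], match = evals[[best_idx]]$match)
  trace <- list(best$fit)
  stall <- 0L
  for (gen in seq_len(config$max_generations - 1L)) {
    ord <- lexical_order(P)
    rank <- integer(nrow(P)); rank[ord] <- seq_along(ord)
    newpop <- matrix(0, config$population_size, p)
    newpop[1, ] <- best$w  # elitism
    for (i in 2:config$population_size) {
      pick <- function() {
        cand <- sample.int(nrow(pop), 2L)
        cand[which.min(rank[cand])]
      }
      pa <- pop[pick(), ]; pb <- pop[pick(), ]
      a <- stats::runif(p, -0.1, 1.1)
      child <- a * pa + (1 - a) * pb
      mut <- stats::runif(p) < config$mutation_rate
      child[mut] <- child[mut] * exp(stats::rnorm(sum(mut), 0, config$mutation_sd))
      newpop[i, ] <- clamp(child, lo, hi)
    }
    pop <- newpop
    evals <- apply(pop, 1, evaluate)
    P <- t(vapply(evals, `[[`, numeric(ncol(P)), "fit"))
    gi <- lexical_order(P)[1]
    if (lexical_compare(P[gi, ], best$fit) == "a_better") {
      best <- list(w = pop[gi, ], fit = P[gi, ], match = evals[[gi]]$match)
      stall <- 0L
    } else stall <- stall + 1L
    trace[[length(trace) + 1L]] <- best$fit
    if (stall >= config$stall_generations) break
  }
  m <- best$match
  m$weight_vector <- stats::setNames(best$w, colnames(prep$Z))
  m$fitness_trace <- trace
  m$best_fitness <- best$fit
  m
}

#' @export
print.rw_match <- function(x, ...) {
  cat(sprintf("rw_match: %d matched pairs (%d treated unmatched)\n",
              x$n_matched, x$n_unmatched))
  if (!is.null(x$best_fitness))
    cat(sprintf("  worst balance p-value: %.4f\n", x$best_fitness[1]))
  invisible(x)
}
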