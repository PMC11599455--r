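# rwcea — real-world cost-effectiveness of a multi-gene testing strategy

`rwcea` is an R package plus analysis workflow for estimating, from
patient-level administrative follow-up data, whether a newer diagnostic
strategy (a multi-gene sequencing panel, $1200 per test) is cost-effective
against an older one (single-gene testing, $228) when treatment assignment
is confounded and follow-up is censored. It is aimed at health-economics and
biostatistics researchers working with linked administrative cohorts, and it
ships a synthetic cohort generator with a known data-generating process so
that every stage of the analysis can be validated without access to
confidential data.

The chain:

1. **Genetic matching** — 1:1 nearest-neighbour matching of treated to
   control patients on a generalized weighted Mahalanobis distance
   `d(x_i,x_j) = sqrt((x_i−x_j)' M' diag(w) M (x_i−x_j))` (`M` the inverse
   Cholesky factor of the pooled covariate covariance, propensity score
   appended), inside exact-matching strata. The weights `w` are evolved by a
   genetic algorithm that lexically maximizes the sorted vector of balance
   p-values (bootstrapped Kolmogorov–Smirnov and paired t tests), the
   worst-balanced covariate first.
2. **Balance diagnostics** — absolute standardized mean differences against
   the pooled pre-match SD, orientation-free variance ratios, KS statistics;
   pass rule SMD < 0.1 and variance ratio < 2.
3. **Survival** — Kaplan–Meier (restricted 3-year means, log-log CIs),
   log-rank, and Weibull regression converted to the hazard-ratio scale
   (`log HR = −β/σ`, HR < 1 favouring the newer test).
4. **Censored costs and life-years** — the partitioned estimator over
   monthly intervals (365.25/12 days) with inverse-probability-of-censoring
   weights `1/Ĝ(min(T, interval end)⁻)` from a per-arm reverse Kaplan–Meier
   curve; costs and life-years discounted at 1.5%/year with interval-start
   factors. ΔC and ΔE are arm differences of the weighted means (identical,
   by construction, to a weighted regression on the arm indicator).
5. **Decision uncertainty** — a nonparametric bootstrap that resamples
   matched pairs, recomputing weights and estimates per replicate;
   incremental net monetary benefit `INMB(λ) = λ·ΔE − ΔC` at $50k and
   $100k/LYG with bias-corrected percentile intervals, the CEAC, and
   cost-effectiveness-plane quadrant proportions, plus a sensitivity suite
   (replacement-capped matching, region exact-match variants, reduced test
   cost, societal perspective, 1–2-year horizons, test-result subgroups,
   SUR estimation).

## Worked example

The numbered scripts under `analysis/` run the full study on the default
synthetic cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_match.R
Rscript analysis/03_balance.R
Rscript analysis/04_survival.R
Rscript analysis/05_costeff.R
Rscript analysis/06_sensitivity.R
```

Output of the run shipped in this repository:

```
Simulated 2172 patients: 950 treated (43.7%), 1222 controls.
Censored: 30.9% treated, 27.6% control.
Generator truth (discounted, 3y): delta C = $6861, delta E = 0.059 LY, HR = 0.932.

Matched 890 of 950 treated patients (93.7%).
Max |SMD|: 0.220 unmatched -> 0.084 matched.

Weibull PH fit: shape 0.960, baseline scale 515.4 days
Hazard ratio (treated vs control): 0.931 [95% CI: 0.833-1.040]
Log-rank p-value: 0.201.
Restricted mean survival (3y): treated 477 d, control 452 d.

Bootstrap cost-effectiveness result (B = 1000, 890 pairs)
  delta C: $3670 [-6262, 12560]
  delta E: 0.067 LY [-0.036, 0.164]
  INMB at $50,000/LYG: $-298 [-7124, 6690], P(CE) = 46.6%
  INMB at $100,000/LYG: $3074 [-4410, 10165], P(CE) = 78.0%
  plane quadrants: NE 75.5%, SE 15.2%, NW 1.9%, SW 7.4%
```

Reading this: matching retains 93.7% of treated patients and brings every
covariate under the SMD < 0.1 criterion (one variance ratio, time since
diagnosis, sits at the 2.0 boundary — `results/balance.csv` has the full
table). The newer test shows a small,
non-significant survival advantage (HR 0.931, ~25 days of restricted mean
survival) at a small, non-significant extra cost (ΔC $3670, mostly the test
price difference plus therapy uptake). At $50,000 per life-year gained the
net monetary benefit is indistinguishable from zero; at $100,000 the
probability of cost-effectiveness reaches 78%, with three-quarters of
bootstrap draws in the "more effective & more costly" quadrant and 15% in
the dominant quadrant. The generator's censoring-free truth (ΔC $6861,
ΔE 0.059) sits inside the bootstrap intervals — the uncertainty is real,
not an estimator artifact.

The same pipeline runs as one call:

```r
library(rwcea)
res <- run_pipeline(run_config(out_dir = "results", B = 1000, master_seed = 1,
                               scenarios = c("base", "reduced_test_cost")))
```

`vignettes/rwcea-methods.Rmd` documents the model, estimator conventions,
and the synthetic generator's assumptions and limits.

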