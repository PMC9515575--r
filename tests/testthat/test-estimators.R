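# Build a factual-only benchmark dataset straight from a fixture cohort:
# real covariates, real confounded (or randomized) treatments, real outcomes
# whose injected per-arm effects are the oracle.
fixture_po <- function(fx) {
  em <- encode(fx$cohort)
  part <- partition(em)
  Xc <- em$data[, part$covariate_cols, drop = FALSE]
  out <- data.frame(Xc, check.names = FALSE)
  out$treatment <- treatment_of(em, part)
  out$y_factual <- outcome_delta(em)
  structure(out, class = c("potential_outcome_table", "data.frame"),
            reference = "t0")
}

test_that("single-stratum stratification equals the unadjusted contrast exactly", {
  fx <- small_fixture(n = 300, arms = 3, seed = 31)
  po <- fixture_po(fx)
  cfg1 <- benchmark_config(n_strata = 1)
  strat <- estimate_ates(po, "propensity_stratification", cfg1)$ate
  unadj <- estimate_ates(po, "unadjusted", cfg1)$ate
  expect_identical(strat, unadj)
  # and by hand for one arm
  a <- names(strat)[1]
  rows_a <- po$treatment == a; rows_0 <- po$treatment == "t0"
  expect_equal(unname(strat[a]),
               mean(po$y_factual[rows_a]) - mean(po$y_factual[rows_0]))
})

test_that("matching equals a brute-force paired oracle on a hand-matchable fixture", {
  # 8 treated + 8 controls on one covariate; with-replacement 1:1 matching
  set.seed(33)
  x <- c(seq(0.1, 0.8, by = 0.1), seq(0.12, 0.82, by = 0.1))
  t01 <- rep(c("a", "t0"), each = 8)
  y <- ifelse(t01 == "a", 5 + 2 * x, 1 + 2 * x)
  po <- structure(data.frame(x = x, treatment = t01, y_factual = y),
                  class = c("potential_outcome_table", "data.frame"),
                  reference = "t0")
  est <- estimate_ates(po, "propensity_matching",
                       benchmark_config(caliper = Inf))$ate
  # oracle: logistic propensity on x, each treated paired with the control
  # whose logit-propensity is nearest (ties to the first)
  e <- stats::fitted(stats::glm((t01 == "a") ~ x, family = binomial()))
  e <- pmin(pmax(e, 0.01), 0.99)
  lp <- stats::qlogis(e)
  it <- which(t01 == "a"); ic <- which(t01 == "t0")
  pair_diff <- vapply(it, function(i) {
    j <- ic[which.min(abs(lp[ic] - lp[i]))]
    y[i] - y[j]
  }, 0)
  expect_equal(unname(est["a"]), mean(pair_diff))
})

test_that("all four estimators are unbiased under randomization (3 SE)", {
  fx <- simulate_cohort(fixture_config(n = 3000, n_treatments = 3,
                                       confounding_strength = 0,
                                       true_effects = c(0, -5, -10),
                                       outcome_noise_sd = 4, seed = 35))
  po <- fixture_po(fx)
  y <- po$y_factual; tr <- po$treatment
  cfg <- benchmark_config(num_trees = 100)
  for (est in c("iptw", "propensity_matching", "propensity_stratification",
                "doubly_robust_rf")) {
    a <- estimate_ates(po, est, cfg)$ate
    for (arm in names(a)) {
      se <- sqrt(stats::var(y[tr == arm]) / sum(tr == arm) +
                   stats::var(y[tr == "t0"]) / sum(tr == "t0"))
      expect_lt(abs(a[arm] - fx$truth[arm]), 3 * se)
    }
  }
})

test_that("positivity failure is flagged, not silently dropped", {
  # deterministic assignment by a covariate threshold: no overlap at all
  set.seed(36)
  x <- runif(300)
  tr <- ifelse(x > 0.5, "a", "t0")
  po <- structure(data.frame(x = x, treatment = tr,
                             y_factual = rnorm(300)),
                  class = c("potential_outcome_table", "data.frame"),
                  reference = "t0")
  est <- estimate_ates(po, "iptw", benchmark_config())
  expect_match(unlist(est$flags), "positivity")
  # an arm with no reference rows at all errors loudly
  po2 <- po; po2$treatment[po2$treatment == "t0"] <- "b"
  expect_error(estimate_ates(po2, "iptw"), "reference")
})

test_that("the benchmark report scores every requested estimator", {
  fx <- simulate_cohort(fixture_config(n = 1200, n_treatments = 4,
                                       confounding_strength = 0.5,
                                       true_effects = c(0, -4, -8, -2),
                                       outcome_noise_sd = 4, seed = 37))
  po <- fixture_po(fx)
  rep_ <- benchmark_estimators(po, truth = fx$truth,
                               estimators = c("doubly_robust_rf", "iptw"),
                               config = benchmark_config(num_trees = 60))
  expect_identical(rep_$table$estimator, c("doubly_robust_rf", "iptw"))
  expect_true(all(abs(rep_$table$spearman) <= 1))
  expect_true(all(rep_$table$r2 <= 1))
  # doubly robust recovers the ranking under mild confounding
  expect_gte(rep_$table$spearman[1], 0.5)
})
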