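fit_small <- function(n = 800, seed = 1, epochs = 120, arms = 4, ...) {
  fx <- simulate_cohort(fixture_config(n = n, n_treatments = arms,
                                       true_effects = c(0, -5, -10, -2),
                                       outcome_noise_sd = 1, seed = seed,
                                       ...))
  em <- encode(fx$cohort)
  part <- partition(em)
  net <- fit_outcome(em, part, outcome_config(epochs = epochs, seed = seed),
                     check_additivity = FALSE)
  list(fx = fx, em = em, part = part, net = net)
}

test_that("effect extraction reads the treatment weights with tau(t0) = 0", {
  s <- fit_small(epochs = 5)
  s$net$w[] <- c(-3.2, -7.1, 4.4)
  tau <- extract_effects(s$net)
  expect_equal(unname(tau[s$part$reference]), 0)
  expect_equal(unname(tau[names(s$net$w)]), c(-3.2, -7.1, 4.4))
  # additivity: forcing treatment A minus forcing t0 equals tau(A) for all x
  pA <- predict_outcome(s$net, s$em, s$part, treatment = names(s$net$w)[1])
  p0 <- predict_outcome(s$net, s$em, s$part, treatment = s$part$reference)
  expect_equal(unname(pA - p0), rep(-3.2, nrow(s$em$data)))
  # the ATE integral collapses: mean contrast over any covariate sample
  expect_equal(mean(pA - p0), -3.2)
})

test_that("noise-free generation makes the per-patient contrast exactly tau", {
  s <- fit_small(epochs = 30)
  po <- generate_outcomes(s$net, s$em, s$part, noise_sigma = 0)
  tau <- extract_effects(s$net)
  contrast <- po$y_factual - po$y_counterfactual_t0
  expect_lt(max(abs(contrast - tau[po$treatment])), 1e-6)
  # untreated patients: factual equals counterfactual
  untreated <- po$treatment == s$part$reference
  expect_true(any(untreated))
  expect_equal(po$y_factual[untreated], po$y_counterfactual_t0[untreated])
  # ITE = ATE on arbitrary subsamples
  set.seed(2)
  for (k in 1:3) {
    idx <- sample(nrow(po), 50)
    sub <- po[idx, ]
    for (a in setdiff(unique(sub$treatment), s$part$reference)) {
      rows <- sub$treatment == a
      expect_lt(max(abs((sub$y_factual - sub$y_counterfactual_t0)[rows] -
                          tau[a])), 1e-6)
    }
  }
})

test_that("generated outcome noise is honest: per-arm contrast within CLT bounds", {
  s <- fit_small(n = 600, epochs = 10)
  po <- generate_outcomes(s$net, s$em, s$part, noise_sigma = 1, seed = 5)
  tau <- extract_effects(s$net)
  for (a in setdiff(unique(po$treatment), s$part$reference)) {
    rows <- po$treatment == a
    m <- mean((po$y_factual - po$y_counterfactual_t0)[rows])
    # two independent noise draws => sd sqrt(2) per contrast
    expect_lt(abs(m - tau[a]), 3 * sqrt(2) / sqrt(sum(rows)) + 1e-9)
  }
})

test_that("zero-epoch fitting returns the seeded initialization (no silent training)", {
  s1 <- fit_small(epochs = 0)
  s2 <- fit_small(epochs = 0)
  expect_identical(s1$net$w, s2$net$w)
  expect_lt(max(abs(s1$net$w)), 0.05)
})

test_that("fitting is deterministic given data, config and seed", {
  s1 <- fit_small(n = 400, epochs = 15)
  s2 <- fit_small(n = 400, epochs = 15)
  expect_identical(s1$net$w, s2$net$w)
  expect_identical(s1$net$phi$W, s2$net$phi$W)
})

test_that("hybrid dataset keeps original covariates and the same ground truth", {
  s <- fit_small(epochs = 10)
  hy <- build_hybrid(s$net, s$em, s$part, noise_sigma = 0)
  cov_names <- colnames(s$em$data)[s$part$covariate_cols]
  hymat <- as.matrix(hy[cov_names])
  rownames(hymat) <- NULL
  expect_identical(hymat, s$em$data[, s$part$covariate_cols])
  expect_identical(nrow(hy), nrow(s$em$data))
  expect_equal(attr(hy, "effects"), extract_effects(s$net))
})

test_that("a covariate-by-treatment interaction fires the heterogeneity warning", {
  fx <- simulate_cohort(fixture_config(n = 3000, n_treatments = 3,
                                       true_effects = c(0, -5, -10),
                                       outcome_noise_sd = 1, seed = 4))
  em <- encode(fx$cohort)
  part <- partition(em)
  # inject a strong interaction: effect scales with baseline blood pressure
  cm <- em$colmap
  pre_col <- cm$col[cm$variable == "sbp_pre" & cm$role == "value"]
  drug <- treatment_of(em, part)
  post_col <- cm$col[cm$variable == "sbp_post" & cm$role == "value"]
  bump <- ifelse(drug == "d01", -20 * em$data[, pre_col], 0)
  em$data[, post_col] <- pmin(pmax(em$data[, post_col] + bump / 220, 0), 1)
  expect_warning(
    fit_outcome(em, part, outcome_config(epochs = 60, seed = 1),
                check_additivity = TRUE),
    "heterogeneity")
})

test_that("outcome tables export with their effects sidecar", {
  s <- fit_small(n = 400, epochs = 5)
  po <- generate_outcomes(s$net, s$em, s$part, noise_sigma = 0)
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_outcomes(po, csv, effects_path = js)
  eff <- jsonlite::read_json(js)
  expect_equal(unlist(eff), unclass(extract_effects(s$net))[names(eff)],
               tolerance = 1e-12)
  back <- utils::read.csv(csv)
  expect_identical(nrow(back), nrow(po))
})
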