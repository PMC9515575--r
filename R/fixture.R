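# Fixture cohort simulator: a stand-in "original" cohort with the
# statistical structure of a multi-arm hypertension claims extract — mixed
# continuous/categorical/date covariates, per-lab missingness, confounded
# softmax treatment assignment over the arms, and additive outcomes (change
# in systolic blood pressure) with known injected effects. It makes every
# other module testable without any external data; it does not attempt to
# match any real cohort's marginal distributions.

#' Fixture cohort configuration
#'
#' @param n Cohort size (must be at least `20 * n_treatments` so every arm
#'   is populated with high probability).
#' @param n_treatments Number of arms including the no-treatment reference
#'   `t0` (default 11: ten drugs plus no treatment).
#' @param n_labs Number of auxiliary lab variables with missingness.
#' @param missingness_rate Per-lab probability of a missing value.
#' @param confounding_strength Scale of the covariate coefficients in the
#'   softmax assignment model; 0 gives uniform randomization (positivity by
#'   construction).
#' @param true_effects Injected effect vector in mmHg of blood-pressure
#'   change, length `n_treatments`, first entry 0 (the reference). The
#'   default spans 0 to -15 mmHg, the clinically plausible range for
#'   antihypertensive monotherapy.
#' @param outcome_noise_sd Std-dev of the additive outcome noise (mmHg).
#' @param baseline_fn `"linear"` or `"nonlinear"` covariate contribution
#'   `f(x_c)` to the outcome.
#' @param seed RNG seed; the whole cohort is reproducible from it.
#' @return A `fixture_config` list.
#' @export
fixture_config <- function(n = 5000, n_treatments = 11, n_labs = 4,
                           missingness_rate = 0.3, confounding_strength = 1,
                           true_effects = NULL, outcome_noise_sd = 8,
                           baseline_fn = c("linear", "nonlinear"), seed = 1) {
  baseline_fn <- match.arg(baseline_fn)
  if (is.null(true_effects))
    true_effects <- round(seq(0, -15, length.out = n_treatments), 2)
  stopifnot(n >= 20 * n_treatments, n_treatments >= 2,
            missingness_rate >= 0, missingness_rate < 1,
            length(true_effects) == n_treatments, true_effects[1] == 0,
            outcome_noise_sd >= 0)
  structure(list(n = n, n_treatments = n_treatments, n_labs = n_labs,
                 missingness_rate = missingness_rate,
                 confounding_strength = confounding_strength,
                 true_effects = true_effects,
                 outcome_noise_sd = outcome_noise_sd,
                 baseline_fn = baseline_fn, seed = seed),
            class = "fixture_config")
}

fixture_schema <- function(config) {
  arms <- c("t0", sprintf("d%02d", seq_len(config$n_treatments - 1)))
  lab_names <- paste0("lab", seq_len(config$n_labs))
  specs <- c(
    list(
      variable_spec("date_pre", "date", family = "F1",
                    range = c("2015-01-01", "2020-12-31")),
      variable_spec("sbp_pre", "continuous", family = "F1",
                    range = c(100, 210), role = "pre_lab"),
      variable_spec("date_post", "date", family = "F2",
                    range = c("2015-01-31", "2021-12-31")),
      variable_spec("sbp_post", "continuous", family = "F2",
                    range = c(40, 260), role = "post_lab"),
      variable_spec("drugs", "categorical", family = "F3",
                    categories = arms, role = "treatment",
                    reference = "t0"),
      variable_spec("prior_drugs", "categorical", family = "F3",
                    categories = c("none", "dA", "dB"), covariate = FALSE),
      variable_spec("age", "continuous", family = "F4", range = c(18, 85)),
      variable_spec("gndr_cd", "categorical", family = "F4",
                    categories = c("F", "M")),
      variable_spec("race_cd", "categorical", family = "F4",
                    categories = c("r1", "r2", "r3", "r4"))),
    lapply(lab_names, function(nm)
      variable_spec(nm, "continuous", family = "F5", range = c(0, 300),
                    missingness_allowed = TRUE)),
    list(
      variable_spec("lab1_date", "date", family = "F5",
                    range = c("2014-01-01", "2020-12-31"),
                    missingness_allowed = TRUE),
      variable_spec("safety_morbs", "binary", family = "F6"),
      variable_spec("morbs_prior", "binary", family = "F6"),
      variable_spec("zip_cd", "categorical", family = "F7",
                    categories = paste0("z", 1:5), covariate = FALSE),
      variable_spec("median_income", "continuous", family = "F7",
                    range = c(20000, 150000))))
  cohort_schema(specs)
}

rtrunc_norm <- function(n, mean, sd, lo, hi)
  pmin(pmax(stats::rnorm(n, mean, sd), lo), hi)

#' Simulate a fixture cohort with known ground-truth effects
#'
#' Covariates are drawn from simple parametric families; the treatment arm
#' is drawn from a softmax over a linear score of age, baseline blood
#' pressure and the comorbidity flags (scaled by `confounding_strength`, so
#' the variables a clinician would adjust for genuinely confound
#' assignment); and the outcome is generated additively as
#' `sbp_post = sbp_pre + f(x_c) + tau(t) + noise`. Every arm is checked to
#' be populated (resimulated with a sub-seed otherwise, with a message).
#'
#' @param config A [fixture_config()].
#' @return A `fixture_cohort`: list with `cohort` (a [cohort_table()]),
#'   `schema`, `truth` (a `ground_truth_effects` vector), and
#'   `assignment_propensities` (N x arms matrix).
#' @export
simulate_cohort <- function(config = fixture_config()) {
  stopifnot(inherits(config, "fixture_config"))
  schema <- fixture_schema(config)
  arms <- schema$specs$drugs$categories
  k <- length(arms)
  for (try_ in 0:4) {
    set.seed(config$seed + 1000L * try_)
    n <- config$n
    age <- round(rtrunc_norm(n, 58, 13, 18, 85), 1)
    sbp_pre <- round(rtrunc_norm(n, 152, 15, 100, 210), 1)
    gndr <- sample(c("F", "M"), n, replace = TRUE)
    race <- sample(paste0("r", 1:4), n, replace = TRUE,
                   prob = c(0.6, 0.2, 0.12, 0.08))
    morb1 <- stats::rbinom(n, 1, 0.25)
    morb2 <- stats::rbinom(n, 1, 0.35)
    income <- round(exp(rtrunc_norm(n, log(60000), 0.4,
                                    log(20000), log(150000))))
    date_pre <- as.Date("2015-01-01") +
      sample.int(2100, n, replace = TRUE) - 1
    date_post <- date_pre + 30 + sample.int(335, n, replace = TRUE)
    labs <- lapply(seq_len(config$n_labs), function(j) {
      v <- round(rtrunc_norm(n, 80 + 25 * j, 30, 0, 300), 1)
      v[stats::runif(n) < config$missingness_rate] <- NA
      v
    })
    names(labs) <- paste0("lab", seq_len(config$n_labs))
    lab1_date <- as.Date("2014-06-01") + sample.int(2300, n, TRUE) - 1
    lab1_date[is.na(labs[[1]])] <- NA
    prior <- sample(c("none", "dA", "dB"), n, TRUE, prob = c(0.6, 0.25, 0.15))
    zip <- sample(paste0("z", 1:5), n, TRUE)
    # confounded assignment: softmax over a linear score of the clinical
    # covariates; coefficients drawn once from the seed, zero for t0
    age_s <- (age - 58) / 13
    sbp_s <- (sbp_pre - 152) / 15
    gamma <- matrix(stats::rnorm(4 * (k - 1), sd = 0.5), nrow = 4)
    score <- cbind(0, cbind(age_s, sbp_s, morb1, morb2) %*% gamma) *
      config$confounding_strength
    pmat <- exp(score - apply(score, 1, max))
    pmat <- pmat / rowSums(pmat)
    colnames(pmat) <- arms
    drug <- arms[vapply(seq_len(n), function(i)
      sample.int(k, 1, prob = pmat[i, ]), 0L)]
    if (!all(arms %in% drug)) {
      message("fixture: empty arm with seed ", config$seed + 1000L * try_,
              "; resimulating with a sub-seed")
      next
    }
    f_x <- -3 * sbp_s - 1.2 * age_s + 1.5 * morb1 + 1 * morb2 +
      if (config$baseline_fn == "nonlinear")
        2 * sin(sbp_s) + 1.5 * pmax(age_s, 0)^2 else 0
    tau <- stats::setNames(config$true_effects, arms)
    delta <- f_x + tau[drug] + stats::rnorm(n, sd = config$outcome_noise_sd)
    sbp_post <- round(pmin(pmax(sbp_pre + delta, 40), 260), 1)
    df <- data.frame(date_pre = date_pre, sbp_pre = sbp_pre,
                     date_post = date_post, sbp_post = sbp_post,
                     drugs = drug, prior_drugs = prior, age = age,
                     gndr_cd = gndr, race_cd = race,
                     stringsAsFactors = FALSE)
    for (nm in names(labs)) df[[nm]] <- labs[[nm]]
    df$lab1_date <- lab1_date
    df$safety_morbs <- morb1
    df$morbs_prior <- morb2
    df$zip_cd <- zip
    df$median_income <- income
    truth <- structure(tau, class = "ground_truth_effects",
                       reference = "t0")
    return(structure(list(cohort = cohort_table(df, schema),
                          schema = schema, truth = truth,
                          assignment_propensities = pmat,
                          config = config),
                     class = "fixture_cohort"))
  }
  stop("fixture: an arm stayed empty after 5 seeds; increase n ",
       "(n = ", config$n, ", arms = ", k, ")")
}

#' @export
print.fixture_cohort <- function(x, ...) {
  cat("fixture_cohort:", nrow(x$cohort$data), "patients,",
      x$config$n_treatments, "arms, injected effects ",
      paste(x$truth, collapse = " "), "\n")
  invisible(x)
}

#' Injected ground-truth effects of a fixture cohort
#'
#' @param fixture A `fixture_cohort`.
#' @return The `ground_truth_effects` vector the outcome was generated with
#'   (reference `t0` first, value 0).
#' @export
ground_truth <- function(fixture) {
  stopifnot(inherits(fixture, "fixture_cohort"))
  fixture$truth
}
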