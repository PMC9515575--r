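# Benchmark suite: four classical average-treatment-effect estimators run on
# factual-only data (counterfactuals removed so the problem is not trivial),
# evaluated against the known ground-truth effects with four metrics.
# Each treatment arm is estimated pairwise against the no-treatment group:
# a binary logistic propensity model on the covariates, then IPTW
# (Horvitz-Thompson), 1:1 propensity matching with replacement, propensity
# stratification on quantile strata, or AIPW with random-forest outcome
# regressions (doubly robust).

#' Benchmark configuration
#'
#' @param n_strata Quantile strata for propensity stratification (default 5,
#'   the classic quintiles; 1 collapses to the unadjusted difference in
#'   means).
#' @param caliper Matching caliper as a multiple of the standard deviation
#'   of the logit propensity (default 0.2); `Inf` disables it.
#' @param clip Propensity scores are clipped to `[clip, 1 - clip]`.
#' @param num_trees Trees for the random-forest outcome regressions.
#' @param seed Seed for the random forest (grown single-threaded so results
#'   are reproducible).
#' @return A `benchmark_config` list.
#' @export
benchmark_config <- function(n_strata = 5, caliper = 0.2, clip = 0.01,
                             num_trees = 200, seed = 1) {
  stopifnot(n_strata >= 1, clip > 0, clip < 0.5)
  structure(list(n_strata = n_strata, caliper = caliper, clip = clip,
                 num_trees = num_trees, seed = seed),
            class = "benchmark_config")
}

#' Estimators available in the benchmark
#' @export
ESTIMATORS <- c("iptw", "propensity_matching", "propensity_stratification",
                "doubly_robust_rf", "unadjusted")

po_components <- function(dataset) {
  stopifnot(inherits(dataset, "potential_outcome_table") ||
              is.data.frame(dataset))
  stopifnot(all(c("treatment", "y_factual") %in% names(dataset)))
  xcols <- setdiff(names(dataset),
                   c("treatment", "y_factual", "y_counterfactual_t0"))
  list(X = as.matrix(dataset[xcols]),
       treatment = as.character(dataset$treatment),
       y = dataset$y_factual,
       reference = attr(dataset, "reference") %||% "t0")
}

fit_propensity <- function(X, t01, clip) {
  df <- data.frame(X, check.names = TRUE)
  df$..t <- t01
  fit <- suppressWarnings(stats::glm(..t ~ ., data = df,
                                     family = stats::binomial()))
  e_raw <- as.numeric(stats::fitted(fit))
  list(e = pmin(pmax(e_raw, clip), 1 - clip),
       clipped = mean(e_raw < clip | e_raw > 1 - clip))
}

ate_one_arm <- function(X, t01, y, estimator, config) {
  flag <- character(0)
  if (sum(t01) == 0 || sum(1 - t01) == 0)
    return(list(ate = NA_real_, flags = "empty group"))
  if (estimator == "unadjusted")
    return(list(ate = mean(y[t01 == 1]) - mean(y[t01 == 0]), flags = flag))
  pr <- fit_propensity(X, t01, config$clip)
  e <- pr$e
  if (pr$clipped > 0.05)
    flag <- c(flag, sprintf("positivity: %.0f%% of propensities clipped",
                            100 * pr$clipped))
  ate <- switch(estimator,
    iptw = mean(t01 * y / e) - mean((1 - t01) * y / (1 - e)),
    propensity_matching = {
      lp <- stats::qlogis(e)
      cal <- config$caliper * stats::sd(lp)
      it <- which(t01 == 1); ic <- which(t01 == 0)
      d <- abs(outer(lp[it], lp[ic], "-"))
      j <- max.col(-d, ties.method = "first")
      ok <- d[cbind(seq_along(it), j)] <= cal
      if (!any(ok)) {
        flag <- c(flag, "matching: no pairs within caliper")
        NA_real_
      } else {
        if (any(!ok))
          flag <- c(flag, sprintf("matching: %d treated dropped by caliper",
                                  sum(!ok)))
        mean(y[it[ok]] - y[ic[j[ok]]])
      }
    },
    propensity_stratification = {
      ns <- config$n_strata
      if (ns == 1L) {
        mean(y[t01 == 1]) - mean(y[t01 == 0])
      } else {
        br <- unique(stats::quantile(e, probs = seq(0, 1, length.out = ns + 1)))
        s <- cut(e, breaks = br, include.lowest = TRUE)
        est <- 0; wsum <- 0
        for (lev in levels(s)) {
          i <- s == lev
          if (sum(t01[i]) > 0 && sum(1 - t01[i]) > 0) {
            est <- est + sum(i) * (mean(y[i & t01 == 1]) -
                                     mean(y[i & t01 == 0]))
            wsum <- wsum + sum(i)
          } else flag <- c(flag, paste0("stratum ", lev,
                                        " lacks one group; dropped"))
        }
        if (wsum == 0) NA_real_ else est / wsum
      }
    },
    doubly_robust_rf = {
      df <- data.frame(X, check.names = TRUE)
      df$..y <- y
      m1 <- ranger::ranger(..y ~ ., data = df[t01 == 1, , drop = FALSE],
                           num.trees = config$num_trees, seed = config$seed,
                           num.threads = 1)
      m0 <- ranger::ranger(..y ~ ., data = df[t01 == 0, , drop = FALSE],
                           num.trees = config$num_trees, seed = config$seed,
                           num.threads = 1)
      mu1 <- stats::predict(m1, df, num.threads = 1)$predictions
      mu0 <- stats::predict(m0, df, num.threads = 1)$predictions
      mean(mu1 - mu0 + t01 * (y - mu1) / e -
             (1 - t01) * (y - mu0) / (1 - e))
    },
    stop("unknown estimator: ", estimator))
  list(ate = ate, flags = flag)
}

#' Estimate per-arm average treatment effects from factual data
#'
#' Runs one estimator on a factual-only dataset (covariates, assigned
#' treatment, observed outcome). For each treatment arm `a`, only the rows
#' with `t %in% c(a, t0)` are used, a binary propensity is fit by logistic
#' regression (clipped), and the arm's ATE versus no treatment is estimated.
#' Positivity problems (heavy clipping, empty strata, calipered-out matches,
#' empty groups) are flagged per arm, never silently dropped.
#'
#' @param dataset A `potential_outcome_table` (its counterfactual column, if
#'   present, is ignored) or a data frame with covariate columns plus
#'   `treatment` and `y_factual`.
#' @param estimator One of the ids in [ESTIMATORS]: `"iptw"`,
#'   `"propensity_matching"`, `"propensity_stratification"`,
#'   `"doubly_robust_rf"`, or the naive `"unadjusted"` contrast.
#' @param config A [benchmark_config()].
#' @param reference No-treatment level (defaults to the dataset attribute).
#' @return An `ate_estimates` object: list with `ate` (named per-arm vector)
#'   and `flags` (named list of per-arm diagnostics).
#' @export
estimate_ates <- function(dataset, estimator = "doubly_robust_rf",
                          config = benchmark_config(), reference = NULL) {
  estimator <- match.arg(estimator, ESTIMATORS)
  pc <- po_components(dataset)
  if (!is.null(reference)) pc$reference <- reference
  arms <- setdiff(sort(unique(pc$treatment)), pc$reference)
  if (!any(pc$treatment == pc$reference))
    stop("no rows carry the reference (no-treatment) level '",
         pc$reference, "'")
  ate <- stats::setNames(numeric(length(arms)), arms)
  flags <- stats::setNames(vector("list", length(arms)), arms)
  for (a in arms) {
    keep <- pc$treatment %in% c(a, pc$reference)
    res <- ate_one_arm(pc$X[keep, , drop = FALSE],
                       as.numeric(pc$treatment[keep] == a),
                       pc$y[keep], estimator, config)
    ate[a] <- res$ate
    flags[[a]] <- res$flags
  }
  structure(list(ate = ate, flags = flags, estimator = estimator),
            class = "ate_estimates")
}

#' @export
print.ate_estimates <- function(x, ...) {
  cat("ATE estimates (", x$estimator, "):\n", sep = "")
  print(round(x$ate, 3))
  fl <- unlist(x$flags)
  if (length(fl)) cat("flags:", paste(fl, collapse = "; "), "\n")
  invisible(x)
}

#' Agreement metrics between estimated and true effects
#'
#' Spearman and Kendall rank correlations, Pearson correlation, and
#' `R^2 = 1 - SS_res / SS_tot` with the ground truth as target and the
#' estimates as predictions (so a constant shift preserves all three
#' correlations but lowers `R^2`). Constant estimates make the correlations
#' undefined; they are reported as 0 with `degenerate = TRUE`.
#'
#' @param estimates Named per-arm vector (or `ate_estimates`).
#' @param truth A `ground_truth_effects` or named vector; the reference
#'   level is dropped before comparison.
#' @return A `rank_metrics` list: `spearman`, `kendalltau`, `pearson`, `r2`,
#'   `degenerate`.
#' @export
rank_metrics <- function(estimates, truth) {
  if (inherits(estimates, "ate_estimates")) estimates <- estimates$ate
  tr <- as.numeric(truth); names(tr) <- names(truth)
  ref <- attr(truth, "reference")
  if (!is.null(ref)) tr <- tr[setdiff(names(tr), ref)]
  common <- intersect(names(estimates), names(tr))
  if (length(common) < 3) stop("need >= 3 treatment arms, got ",
                               length(common))
  est <- estimates[common]; tr <- tr[common]
  keep <- is.finite(est)
  est <- est[keep]; tr <- tr[keep]
  degenerate <- stats::sd(est) == 0 || length(est) < 3
  corr <- function(m) if (degenerate) 0 else
    suppressWarnings(stats::cor(est, tr, method = m))
  r2 <- 1 - sum((tr - est)^2) / sum((tr - mean(tr))^2)
  structure(list(spearman = corr("spearman"), kendalltau = corr("kendall"),
                 pearson = corr("pearson"), r2 = r2,
                 degenerate = degenerate, n_arms = length(est)),
            class = "rank_metrics")
}

#' @export
print.rank_metrics <- function(x, ...) {
  cat(sprintf("spearman %.3f  kendalltau %.3f  pearson %.3f  R2 %.3f%s\n",
              x$spearman, x$kendalltau, x$pearson, x$r2,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Run the full estimator benchmark
#'
#' Applies each requested estimator to the factual-only dataset and scores
#' it against the ground truth, mirroring the shape of a model-evaluation
#' table (one row per estimator, the four metrics as columns).
#'
#' @param dataset A `potential_outcome_table`.
#' @param truth Ground-truth effects (defaults to the dataset's `effects`
#'   attribute).
#' @param estimators Character vector of estimator ids.
#' @param config A [benchmark_config()].
#' @return A `benchmark_report`: list with `table` (data frame of metrics),
#'   `estimates` (per-estimator `ate_estimates`), `truth`.
#' @export
benchmark_estimators <- function(dataset, truth = attr(dataset, "effects"),
                                 estimators = c("doubly_robust_rf",
                                                "propensity_stratification",
                                                "propensity_matching",
                                                "iptw"),
                                 config = benchmark_config()) {
  stopifnot(!is.null(truth))
  ests <- lapply(estimators, function(e)
    estimate_ates(dataset, e, config,
                  reference = attr(truth, "reference")))
  names(ests) <- estimators
  rows <- lapply(estimators, function(e) {
    m <- rank_metrics(ests[[e]], truth)
    data.frame(estimator = e, spearman = m$spearman,
               kendalltau = m$kendalltau, pearson = m$pearson, r2 = m$r2)
  })
  structure(list(table = do.call(rbind, rows), estimates = ests,
                 truth = truth),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  print(x$table, row.names = FALSE, digits = 3)
  invisible(x)
}
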