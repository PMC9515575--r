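# Realisticity evaluation: empirical 1-Wasserstein distance between encoded
# datasets via exact discrete optimal transport on subsamples, anchored by a
# random-uniform baseline and a split-half best case; correlation heatmap
# matrices; per-variable marginal summaries.

#' Optimal-transport evaluation configuration
#'
#' @param subsample Rows drawn from each dataset per repeat (the assignment
#'   problem is solved exactly at this size). `Inf` disables subsampling
#'   (both datasets are then trimmed to the smaller row count).
#' @param repeats Number of subsample repeats; the mean distance is reported.
#' @param seed RNG seed for the subsampling.
#' @return An `ot_config` list.
#' @export
ot_config <- function(subsample = 1000, repeats = 5, seed = 1) {
  stopifnot(subsample >= 2, repeats >= 1)
  structure(list(subsample = subsample, repeats = repeats, seed = seed),
            class = "ot_config")
}

as_matrix_ <- function(x) if (inherits(x, "encoded_matrix")) x$data else
  as.matrix(x)

# Euclidean cost matrix, row i of A vs rows of B (same arithmetic per pair
# as a direct per-pair computation; exact zeros for identical rows).
cost_matrix <- function(A, B) {
  tB <- t(B)
  out <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    out[i, ] <- sqrt(.colSums((tB - A[i, ])^2, nrow(tB), ncol(tB)))
  out
}

#' Empirical 1-Wasserstein distance between two encoded datasets
#'
#' Estimates the 1-Wasserstein distance under Euclidean ground cost by
#' solving the discrete optimal-transport (assignment) problem exactly on
#' equal-size subsamples, reporting the mean over repeats. With subsampling
#' disabled and `A = B` the distance is exactly 0.
#'
#' @param A,B `encoded_matrix` objects or numeric matrices of equal width.
#' @param config An [ot_config()].
#' @return Nonnegative scalar.
#' @export
wasserstein_estimate <- function(A, B, config = ot_config()) {
  A <- as_matrix_(A); B <- as_matrix_(B)
  if (ncol(A) != ncol(B))
    stop("width mismatch: ", ncol(A), " vs ", ncol(B), " features")
  m <- min(nrow(A), nrow(B), config$subsample)
  full <- m == nrow(A) && m == nrow(B)
  reps <- if (full) 1L else config$repeats
  set.seed(config$seed)
  vals <- numeric(reps)
  for (r in seq_len(reps)) {
    ia <- if (m == nrow(A)) seq_len(m) else sample.int(nrow(A), m)
    ib <- if (m == nrow(B)) seq_len(m) else sample.int(nrow(B), m)
    cm <- cost_matrix(A[ia, , drop = FALSE], B[ib, , drop = FALSE])
    vals[r] <- lapjv_cpp(cm)$total_cost / m
  }
  mean(vals)
}

#' Baseline and best-case Wasserstein anchors
#'
#' The baseline is the distance between the original dataset and an i.i.d.
#' Uniform(0,1) matrix of identical shape (what "random data" looks like on
#' the encoded scale); the best case is the distance between the two halves
#' of a seeded random half/half split of the original (the distance between
#' the dataset and itself, up to sampling noise). After successful training
#' the synthetic distance should fall between the two.
#'
#' @param original An `encoded_matrix` (or matrix), at least 4 rows.
#' @param seed Seed for the uniform draw and the split.
#' @param config An [ot_config()].
#' @return List with `w_baseline` and `w_bestcase`.
#' @export
baseline_and_bestcase <- function(original, seed = 1,
                                  config = ot_config()) {
  X <- as_matrix_(original)
  stopifnot(nrow(X) >= 4)
  set.seed(seed)
  U <- matrix(stats::runif(length(X)), nrow(X))
  half <- sample.int(nrow(X), floor(nrow(X) / 2))
  list(w_baseline = wasserstein_estimate(X, U, config),
       w_bestcase = wasserstein_estimate(X[half, , drop = FALSE],
                                         X[-half, , drop = FALSE], config))
}

#' Variability of the best-case anchor over repeated splits
#'
#' @param original An `encoded_matrix` or matrix.
#' @param n_splits Number of random half/half splits.
#' @param seed Base seed (split k uses `seed + k`).
#' @param config An [ot_config()].
#' @return List with per-split `values` and their coefficient of variation
#'   `cv`.
#' @export
bestcase_split_cv <- function(original, n_splits = 10, seed = 1,
                              config = ot_config()) {
  X <- as_matrix_(original)
  vals <- vapply(seq_len(n_splits), function(k) {
    set.seed(seed + k)
    half <- sample.int(nrow(X), floor(nrow(X) / 2))
    wasserstein_estimate(X[half, , drop = FALSE], X[-half, , drop = FALSE],
                         config)
  }, 0)
  list(values = vals, cv = stats::sd(vals) / mean(vals))
}

safe_cor <- function(A, B = NULL) {
  suppressWarnings(cc <- stats::cor(A, B))
  cc[!is.finite(cc)] <- 0
  # zero-variance columns correlate with nothing, including themselves
  zA <- apply(A, 2, stats::sd) == 0
  zB <- if (is.null(B)) zA else apply(B, 2, stats::sd) == 0
  cc[zA, ] <- 0
  cc[, zB] <- 0
  cc
}

#' Correlation heatmap matrices
#'
#' Within-original and within-synthetic correlation matrices (symmetric,
#' unit diagonal for non-constant columns) plus the cross matrix whose
#' `(j, k)` entry is the correlation of original column `j` against the
#' paired synthetic column `k` (rows paired by generation index). Columns
#' with zero variance yield 0 by convention.
#'
#' @param original,synthetic `encoded_matrix` objects or matrices with the
#'   same number of rows (for the cross matrix) and columns.
#' @return List of `corr_original`, `corr_synthetic`, `corr_cross`.
#' @export
correlation_report <- function(original, synthetic) {
  A <- as_matrix_(original); B <- as_matrix_(synthetic)
  if (nrow(A) != nrow(B))
    stop("row-count mismatch: the cross matrix requires paired rows (",
         nrow(A), " vs ", nrow(B), ")")
  list(corr_original = safe_cor(A),
       corr_synthetic = safe_cor(B),
       corr_cross = safe_cor(A, B))
}

#' Full distribution similarity report
#'
#' Bundles the Wasserstein estimate with its baseline/best-case anchors,
#' the three correlation matrices, and per-column marginal quartile
#' summaries for the original and synthetic datasets.
#'
#' @param original,synthetic `encoded_matrix` objects or matrices.
#' @param config An [ot_config()].
#' @param seed Seed for the anchors.
#' @return A `distribution_report` list.
#' @export
distribution_report <- function(original, synthetic, config = ot_config(),
                                seed = 1) {
  A <- as_matrix_(original); B <- as_matrix_(synthetic)
  anchors <- baseline_and_bestcase(A, seed = seed, config = config)
  marg <- function(M) t(apply(M, 2, stats::quantile,
                              probs = c(0.25, 0.5, 0.75)))
  structure(list(w_synthetic = wasserstein_estimate(A, B, config),
                 w_baseline = anchors$w_baseline,
                 w_bestcase = anchors$w_bestcase,
                 correlations = if (nrow(A) == nrow(B))
                   correlation_report(A, B)
                 else list(corr_original = safe_cor(A),
                           corr_synthetic = safe_cor(B),
                           corr_cross = NULL),
                 marginal_original = marg(A),
                 marginal_synthetic = marg(B)),
            class = "distribution_report")
}

#' @export
print.distribution_report <- function(x, ...) {
  cat(sprintf("Wasserstein: synthetic %.4f (best case %.4f, baseline %.4f)\n",
              x$w_synthetic, x$w_bestcase, x$w_baseline))
  invisible(x)
}
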