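# Separable outcome network: Y = phi(x_c) + w . t + noise, where phi is a
# ReLU multilayer perceptron on the covariates (its output-layer bias is the
# shared intercept) and the treatments are one-hot inputs connected directly
# to the output through a linear weight vector w. Because covariates and
# treatments never interact, the treatment-connection weights ARE the
# individual and population-average treatment effects, and serve as the
# ground truth when the generated data is used to benchmark causal
# estimators. The no-treatment reference is the all-zero treatment vector,
# so tau(t0) = 0 identically.

#' Outcome network configuration
#'
#' @param phi_layers Hidden widths of the covariate branch.
#' @param dropout_rate Dropout probability on the hidden layers during
#'   training (in `[0, 1)`); disabled at generation time.
#' @param l2_coeff L2 regularization applied to all weights.
#' @param learning_rate,epochs,batch_size Adam settings.
#' @param noise_sigma Std-dev of optional additive Gaussian outcome noise at
#'   generation time (default 0 = deterministic outcomes).
#' @param seed RNG seed.
#' @return An `outcome_config` list.
#' @export
outcome_config <- function(phi_layers = c(64, 32), dropout_rate = 0.1,
                           l2_coeff = 1e-5, learning_rate = 5e-3,
                           epochs = 400, batch_size = 256, noise_sigma = 0,
                           seed = 1) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, l2_coeff >= 0,
            noise_sigma >= 0, epochs >= 0)
  structure(list(phi_layers = phi_layers, dropout_rate = dropout_rate,
                 l2_coeff = l2_coeff, learning_rate = learning_rate,
                 epochs = epochs, batch_size = batch_size,
                 noise_sigma = noise_sigma, seed = seed),
            class = "outcome_config")
}

# Treatment design matrix: one column per non-reference level; the reference
# (no-treatment) level is the zero vector.
treatment_design <- function(em, part) {
  lev <- treatment_of(em, part)
  active <- setdiff(part$treatment_levels, part$reference)
  Tm <- matrix(0, nrow(em$data), length(active),
               dimnames = list(NULL, active))
  for (a in active) Tm[lev == a, a] <- 1
  list(Tm = Tm, levels = lev, active = active)
}

#' Fit the separable outcome network
#'
#' Minimizes the mean squared error of `phi(x_c) + w . t` against the
#' observed outcome (post-lab minus pre-lab, on the original measurement
#' scale, e.g. mmHg), with dropout on the hidden layers and L2 on all
#' weights. Trained on the original encoded cohort; seeded and deterministic
#' given the config. With `epochs = 0` the seeded initialization is returned
#' untrained.
#'
#' @param em An `encoded_matrix` of the original cohort.
#' @param part Its [partition()].
#' @param config An [outcome_config()].
#' @param check_additivity If `TRUE`, run a post-fit heterogeneity diagnostic
#'   that warns when residual-covariate slopes differ by treatment arm —
#'   the signature of a covariate-by-treatment interaction, under which the
#'   extracted effects are population-average contrasts rather than
#'   individual-level effects.
#' @return An `outcome_net`: list with `phi` (the covariate `sc_mlp`), `w`
#'   (named treatment-connection weights), `part` bookkeeping and `config`.
#' @export
fit_outcome <- function(em, part = partition(em), config = outcome_config(),
                        check_additivity = TRUE) {
  stopifnot(inherits(em, "encoded_matrix"),
            inherits(part, "domain_partition"))
  y <- outcome_delta(em)
  Xc <- em$data[, part$covariate_cols, drop = FALSE]
  td <- treatment_design(em, part)
  n <- nrow(Xc)
  set.seed(config$seed)
  phi <- mlp_new(ncol(Xc), config$phi_layers, 1, act = "relu",
                 out_act = "linear")
  # start the intercept at the outcome mean so early epochs fit structure,
  # not scale
  phi$b[[phi$L]] <- mean(y)
  w <- stats::rnorm(length(td$active), sd = 0.01)
  names(w) <- td$active
  opt <- adam_new(phi)
  mw <- vw <- numeric(length(w)); tW <- 0L
  bs <- min(config$batch_size, n)
  lr <- config$learning_rate
  steps <- ceiling(n / bs)
  for (epoch in seq_len(config$epochs)) {
    for (s in seq_len(steps)) {
      i <- sample.int(n, bs)
      fw <- mlp_forward(phi, Xc[i, , drop = FALSE],
                        dropout_rate = config$dropout_rate)
      pred <- as.numeric(fw$out) + as.numeric(td$Tm[i, , drop = FALSE] %*% w)
      resid <- pred - y[i]
      if (!all(is.finite(resid)))
        stop("non-finite loss at epoch ", epoch, ", step ", s)
      dOut <- matrix(2 * resid / bs, bs, 1)
      g <- mlp_backward(phi, fw, dOut)
      if (config$l2_coeff > 0)
        for (l in seq_along(g$dW))
          g$dW[[l]] <- g$dW[[l]] + 2 * config$l2_coeff * phi$W[[l]]
      up <- adam_step(phi, opt, g$dW, g$db, lr, beta1 = 0.9, beta2 = 0.999)
      phi <- up$net; opt <- up$opt
      gw <- as.numeric(crossprod(td$Tm[i, , drop = FALSE],
                                 2 * resid / bs)) + 2 * config$l2_coeff * w
      tW <- tW + 1L
      mw <- 0.9 * mw + 0.1 * gw
      vw <- 0.999 * vw + 0.001 * gw^2
      w <- w - lr * (mw / (1 - 0.9^tW)) /
        (sqrt(vw / (1 - 0.999^tW)) + 1e-8)
    }
  }
  net <- structure(list(phi = phi, w = w, part = part, config = config,
                        covariate_names = colnames(em$data)[part$covariate_cols]),
                   class = "outcome_net")
  if (check_additivity && config$epochs > 0)
    check_effect_homogeneity(net, em, part)
  net
}

#' @export
print.outcome_net <- function(x, ...) {
  cat("outcome_net: phi hidden =",
      paste(x$config$phi_layers, collapse = "/"),
      "; treatment effects (ref", x$part$reference, "= 0):\n")
  print(round(x$w, 3))
  invisible(x)
}

# Residual-slope heterogeneity diagnostic: under the additive model the
# residual slope on the fitted covariate index phi(x_c) is the same in every
# arm; a covariate-by-treatment interaction shows up as arm-specific slopes.
# Warns (does not stop) when the interaction F-test is overwhelming.
check_effect_homogeneity <- function(net, em, part, p_cut = 1e-4) {
  res <- outcome_delta(em) - predict_outcome(net, em, part)
  x1 <- as.numeric(mlp_forward(net$phi,
                               em$data[, part$covariate_cols,
                                       drop = FALSE])$out)
  arm <- factor(treatment_of(em, part))
  if (nlevels(arm) < 2 || stats::var(x1) == 0) return(invisible(FALSE))
  full <- stats::lm(res ~ x1 * arm)
  redu <- stats::lm(res ~ x1 + arm)
  p <- stats::anova(redu, full)[2, "Pr(>F)"]
  if (is.finite(p) && p < p_cut)
    warning("covariate-by-treatment heterogeneity detected (p = ",
            signif(p, 2), "); extracted effects are population-average ",
            "contrasts, not individual-level effects", call. = FALSE)
  invisible(is.finite(p) && p < p_cut)
}

#' Predict outcomes under assigned (or forced) treatments
#'
#' Deterministic forward pass `phi(x_c) + w . t` (dropout disabled).
#'
#' @param net An `outcome_net`.
#' @param em An `encoded_matrix` colmap-compatible with the training data.
#' @param part Its partition.
#' @param treatment Optional single treatment level to force on every
#'   patient (default: each patient's assigned treatment).
#' @return Numeric vector of predicted outcomes (original scale).
#' @export
predict_outcome <- function(net, em, part = net$part, treatment = NULL) {
  Xc <- em$data[, part$covariate_cols, drop = FALSE]
  if (!identical(colnames(Xc), net$covariate_names))
    stop("colmap mismatch: covariate columns differ from the training data")
  base <- as.numeric(mlp_forward(net$phi, Xc)$out)
  if (is.null(treatment)) {
    td <- treatment_design(em, part)
    base + as.numeric(td$Tm %*% net$w)
  } else {
    stopifnot(treatment %in% part$treatment_levels)
    base + if (treatment == part$reference) 0 else net$w[[treatment]]
  }
}

#' Extract the ground-truth treatment effects
#'
#' Reads the treatment-connection weights: `tau(t_i) = w_i` exactly, and
#' `tau(t0) = 0` for the no-treatment reference. Because the network is
#' additive (no covariate-treatment interaction), this is simultaneously the
#' individual treatment effect for every covariate value and the population
#' average treatment effect (the ATE integral over the covariate
#' distribution collapses to the constant `w_i`).
#'
#' @param net An `outcome_net`.
#' @return A `ground_truth_effects` object: named numeric vector of effects
#'   (reference level first, value 0).
#' @export
extract_effects <- function(net) {
  tau <- c(0, net$w)
  names(tau) <- c(net$part$reference, names(net$w))
  structure(tau, class = "ground_truth_effects",
            reference = net$part$reference)
}

#' Generate factual and counterfactual outcomes
#'
#' For each patient: the factual outcome under the assigned treatment and the
#' counterfactual outcome had no treatment been received (only these two
#' potential outcomes are generated). Generation is a deterministic forward
#' pass plus optional i.i.d. Gaussian noise added independently to each
#' potential outcome; with `noise_sigma = 0` the per-patient contrast
#' `Y(t) - Y(t0)` equals the extracted effect exactly.
#'
#' @param net An `outcome_net`.
#' @param em Synthetic (or original) `encoded_matrix`, colmap-compatible
#'   with the training data.
#' @param part Its partition.
#' @param noise_sigma Outcome noise std-dev (default from the net's config).
#' @param seed RNG seed for the noise.
#' @return A `potential_outcome_table` data frame: encoded covariates,
#'   `treatment`, `y_factual`, `y_counterfactual_t0`; the ground-truth
#'   effects are attached as attribute `"effects"`.
#' @export
generate_outcomes <- function(net, em, part = net$part,
                              noise_sigma = net$config$noise_sigma,
                              seed = 1) {
  Xc <- em$data[, part$covariate_cols, drop = FALSE]
  if (!identical(colnames(Xc), net$covariate_names))
    stop("colmap mismatch: covariate columns differ from the training data")
  base <- as.numeric(mlp_forward(net$phi, Xc)$out)
  td <- treatment_design(em, part)
  y_f <- base + as.numeric(td$Tm %*% net$w)
  y_cf <- base
  if (noise_sigma > 0) {
    set.seed(seed)
    y_f <- y_f + stats::rnorm(length(y_f), sd = noise_sigma)
    y_cf <- y_cf + stats::rnorm(length(y_cf), sd = noise_sigma)
  }
  out <- data.frame(Xc, check.names = FALSE)
  out$treatment <- td$levels
  out$y_factual <- y_f
  out$y_counterfactual_t0 <- y_cf
  structure(out, class = c("potential_outcome_table", "data.frame"),
            effects = extract_effects(net), reference = part$reference)
}

#' Build the hybrid dataset
#'
#' Original covariates and treatments paired with outcomes generated by the
#' trained outcome network — "hybrid" because the patient variables are real
#' while the outcomes (and hence the ground truth) are generated. Same
#' contrast guarantees as [generate_outcomes()].
#'
#' @inheritParams generate_outcomes
#' @param original The original `encoded_matrix`.
#' @return A `potential_outcome_table`.
#' @export
build_hybrid <- function(net, original, part = net$part,
                         noise_sigma = net$config$noise_sigma, seed = 1) {
  generate_outcomes(net, original, part, noise_sigma = noise_sigma,
                    seed = seed)
}

#' Export a potential-outcome table with its effects sidecar
#'
#' @param po A `potential_outcome_table`.
#' @param path CSV path for the dataset.
#' @param effects_path Optional JSON path for the ground-truth effects.
#' @return Invisibly, `path`.
#' @export
write_outcomes <- function(po, path, effects_path = NULL) {
  utils::write.csv(as.data.frame(po), path, row.names = FALSE)
  if (!is.null(effects_path)) {
    eff <- attr(po, "effects")
    jsonlite::write_json(as.list(eff), effects_path, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}
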