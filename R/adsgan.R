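# Adapted ADS-GAN: a conditional generator G(x, z) and a WGAN-GP critic,
# trained adversarially with an identifiability loss that pushes generated
# records away from their conditioning records, plus a contrastive (triplet)
# hinge that penalizes a generated record for being closer to a random other
# real record than to its own conditioning record.

#' GAN training configuration
#'
#' @param noise_dim Dimension of the Gaussian noise input z (default 32).
#' @param gen_layers,critic_layers Hidden-layer widths of generator/critic.
#' @param mu Gradient-penalty coefficient (default 10).
#' @param lambda Trade-off weight between the adversarial loss and the
#'   identifiability loss (larger = more privacy, less fidelity).
#' @param beta Weight of the contrastive hinge inside the identifiability
#'   loss.
#' @param n_critic Critic updates per generator update (default 5).
#' @param batch_size,epochs,learning_rate Optimization settings (Adam,
#'   beta1 = 0.5, beta2 = 0.9).
#' @param weight_cap Cap for the entropy-derived feature weights used inside
#'   the identifiability distance.
#' @param seed RNG seed; training is deterministic given data + config + seed.
#' @return A `gan_config` list.
#' @export
gan_config <- function(noise_dim = 32, gen_layers = c(64, 64),
                       critic_layers = c(64, 64), mu = 10, lambda = 1,
                       beta = 1, n_critic = 5, batch_size = 128, epochs = 50,
                       learning_rate = 1e-4, weight_cap = 50, seed = 1) {
  stopifnot(mu >= 0, lambda >= 0, beta >= 0, n_critic >= 1, batch_size >= 2,
            epochs >= 1, noise_dim >= 1)
  structure(list(noise_dim = noise_dim, gen_layers = gen_layers,
                 critic_layers = critic_layers, mu = mu, lambda = lambda,
                 beta = beta, n_critic = n_critic, batch_size = batch_size,
                 epochs = epochs, learning_rate = learning_rate,
                 weight_cap = weight_cap, seed = seed),
            class = "gan_config")
}

gen_input <- function(X, Z) cbind(X, Z)

#' Apply a conditional generator
#'
#' @param generator An `sc_mlp` generator (input `d + noise_dim`, sigmoid
#'   output of width `d`) or a plain function `(x, z) -> matrix`.
#' @param X Conditioning records, n x d.
#' @param Z Noise, n x noise_dim.
#' @return n x d matrix of raw generator output in `[0,1]`.
#' @export
generator_apply <- function(generator, X, Z) {
  if (inherits(generator, "sc_mlp"))
    mlp_forward(generator, gen_input(X, Z))$out
  else generator(X, Z)
}

critic_value <- function(critic, X) {
  if (inherits(critic, "sc_mlp")) as.numeric(mlp_forward(critic, X)$out)
  else as.numeric(critic(X))
}

#' WGAN-GP critic loss
#'
#' Evaluates `E[D(x)] - E[D(xhat)] - mu * E[(||grad D(xtilde)||_2 - 1)^2]`,
#' where `xtilde = u*x + (1-u)*xhat` with per-sample `u ~ Uniform(0,1)` is a
#' random interpolation between the real and generated batches. The training
#' loop ascends this quantity for the critic; the generator descends
#' `E[D(x)] - E[D(xhat)]`. For a critic whose input gradient has unit norm
#' everywhere the penalty term is exactly zero; for a constant critic the
#' loss is exactly `-mu`.
#'
#' @param real_batch,fake_batch n x d matrices (equal width).
#' @param critic An `sc_mlp` with scalar output.
#' @param mu Gradient-penalty coefficient.
#' @param interp_u Optional vector of interpolation coefficients (length n);
#'   drawn from the current RNG when `NULL`.
#' @return Scalar loss value.
#' @export
critic_loss <- function(real_batch, fake_batch, critic, mu = 10,
                        interp_u = NULL) {
  if (ncol(real_batch) != ncol(fake_batch))
    stop("width mismatch: real ", ncol(real_batch), " vs fake ",
         ncol(fake_batch))
  n <- min(nrow(real_batch), nrow(fake_batch))
  real_batch <- real_batch[seq_len(n), , drop = FALSE]
  fake_batch <- fake_batch[seq_len(n), , drop = FALSE]
  if (is.null(interp_u)) interp_u <- stats::runif(n)
  Xt <- interp_u * real_batch + (1 - interp_u) * fake_batch
  g <- mlp_input_grad(critic, Xt)
  pen <- mean((sqrt(rowSums(g^2)) - 1)^2)
  mean(critic_value(critic, real_batch)) -
    mean(critic_value(critic, fake_batch)) - mu * pen
}

row_wdist <- function(A, B, wv) sqrt(rowSums((rep(wv, each = nrow(A)) *
                                                (A - B))^2))

#' Contrastive (triplet ranking) loss
#'
#' Per sample, `max(0, U(x, G(x,z)) - U(x', G(x,z)))` averaged over the
#' batch, where `U` is the entropy-weighted distance and `x'` is a randomly
#' drawn negative from the same dataset: zero whenever the generated point is
#' (weakly) closer to its conditioning record than to the negative, and equal
#' to the distance gap otherwise.
#'
#' @param x Anchor batch, n x d.
#' @param x_prime Negative batch, n x d.
#' @param z Noise batch, n x noise_dim.
#' @param generator `sc_mlp` or function `(x, z) -> matrix`.
#' @param w Feature weights ([compute_weights()] object or positive vector).
#' @return Nonnegative scalar.
#' @export
contrastive_loss <- function(x, x_prime, z, generator, w) {
  G <- generator_apply(generator, x, z)
  wv <- as_weight_vector(w, ncol(x))
  mean(pmax(0, row_wdist(x, G, wv) - row_wdist(x_prime, G, wv)))
}

#' Identifiability loss
#'
#' `E[-U(x, G(x,z))] + beta * E[max(0, U(x,G(x,z)) - U(x',G(x,z)))]`. The
#' first term rewards generated records for moving away from their
#' conditioning records (privacy); the contrastive term penalizes them for
#' landing closer to some other real record. For the identity generator both
#' terms are exactly zero; with `beta = 0` it reduces to the plain
#' conditioning-distance term.
#'
#' @param batch Anchor batch, n x d.
#' @param negatives Negative batch, n x d (drawn uniformly from the dataset).
#' @param z_batch Noise batch.
#' @param generator `sc_mlp` or function.
#' @param w Feature weights.
#' @param beta Contrastive weight.
#' @return Scalar loss value.
#' @export
identifiability_loss <- function(batch, negatives, z_batch, generator, w,
                                 beta = 1) {
  G <- generator_apply(generator, batch, z_batch)
  wv <- as_weight_vector(w, ncol(batch))
  u_anchor <- row_wdist(batch, G, wv)
  u_neg <- row_wdist(negatives, G, wv)
  mean(-u_anchor) + beta * mean(pmax(0, u_anchor - u_neg))
}

# d/dG of row_wdist(x, G): w^2 * (G - x) / U per row (0 where U ~ 0)
wdist_grad <- function(x, G, wv, u) {
  s <- ifelse(u > 1e-12, 1 / u, 0)
  (G - x) * rep(wv^2, each = nrow(G)) * s
}

#' Train the adapted ADS-GAN
#'
#' Alternating optimization of `argmin_G max_D [L_D + lambda * L_I]`: per
#' generator step the critic takes `n_critic` gradient-ascent steps on the
#' WGAN-GP loss, then the generator takes one descent step on
#' `-E[D(G(x,z))] + lambda * L_I`. Noise is standard Gaussian. Entropy
#' weights for the identifiability distance are computed once on the
#' original matrix. Deterministic given (data, config).
#'
#' @param original An `encoded_matrix`.
#' @param config A [gan_config()].
#' @return A `generator_bundle`: list with `generator`, `critic`, `config`,
#'   `weights` (feature weights), and `training_log` (per-epoch critic,
#'   generator and identifiability losses).
#' @export
train_adsgan <- function(original, config = gan_config()) {
  stopifnot(inherits(original, "encoded_matrix"),
            inherits(config, "gan_config"))
  X <- original$data
  n <- nrow(X); d <- ncol(X)
  if (n < config$batch_size)
    stop("cohort has ", n, " rows but batch_size is ", config$batch_size)
  w <- compute_weights(X, cap = config$weight_cap)
  wv <- as_weight_vector(w, d)
  set.seed(config$seed)
  gen <- mlp_new(d + config$noise_dim, config$gen_layers, d,
                 act = "relu", out_act = "sigmoid")
  cri <- mlp_new(d, config$critic_layers, 1, act = "tanh",
                 out_act = "linear")
  opt_g <- adam_new(gen); opt_c <- adam_new(cri)
  steps_per_epoch <- ceiling(n / config$batch_size)
  bs <- config$batch_size
  lr <- config$learning_rate
  log_rows <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    last <- c(c_loss = NA_real_, g_loss = NA_real_, i_loss = NA_real_)
    for (step in seq_len(steps_per_epoch)) {
      for (k in seq_len(config$n_critic)) {
        ir <- sample.int(n, bs); icond <- sample.int(n, bs)
        Xr <- X[ir, , drop = FALSE]
        Z <- matrix(stats::rnorm(bs * config$noise_dim), bs)
        Xf <- generator_apply(gen, X[icond, , drop = FALSE], Z)
        u <- stats::runif(bs)
        Xt <- u * Xr + (1 - u) * Xf
        fw_r <- mlp_forward(cri, Xr)
        fw_f <- mlp_forward(cri, Xf)
        g_r <- mlp_backward(cri, fw_r, matrix(1 / bs, bs, 1))
        g_f <- mlp_backward(cri, fw_f, matrix(-1 / bs, bs, 1))
        gp <- mlp_gp_grads(cri, Xt)
        # ascend: E D(real) - E D(fake) - mu * penalty
        dW <- sum_grads(g_r$dW, g_f$dW, scale_grads(gp$dW, -config$mu))
        db <- sum_grads(g_r$db, g_f$db, scale_grads(gp$db, -config$mu))
        up <- adam_step(cri, opt_c, dW, db, lr, maximize = TRUE)
        cri <- up$net; opt_c <- up$opt
        last["c_loss"] <- mean(fw_r$out) - mean(fw_f$out) -
          config$mu * gp$penalty
      }
      ib <- sample.int(n, bs); ineg <- sample.int(n, bs)
      Xb <- X[ib, , drop = FALSE]; Xn <- X[ineg, , drop = FALSE]
      Z <- matrix(stats::rnorm(bs * config$noise_dim), bs)
      fw_g <- mlp_forward(gen, gen_input(Xb, Z))
      G <- fw_g$out
      # adversarial part: descend -E[D(G)]
      dG <- -mlp_input_grad(cri, G) / bs
      i_loss <- NA_real_
      if (config$lambda > 0) {
        u_a <- row_wdist(Xb, G, wv)
        u_n <- row_wdist(Xn, G, wv)
        g_a <- wdist_grad(Xb, G, wv, u_a)
        active <- (u_a - u_n) > 0
        dG_i <- -g_a / bs
        if (any(active)) {
          g_n <- wdist_grad(Xn, G, wv, u_n)
          dG_i[active, ] <- dG_i[active, ] +
            config$beta * (g_a[active, , drop = FALSE] -
                             g_n[active, , drop = FALSE]) / bs
        }
        dG <- dG + config$lambda * dG_i
        i_loss <- mean(-u_a) + config$beta * mean(pmax(0, u_a - u_n))
      }
      gg <- mlp_backward(gen, fw_g, dG)
      up <- adam_step(gen, opt_g, gg$dW, gg$db, lr)
      gen <- up$net; opt_g <- up$opt
      g_loss <- -mean(critic_value(cri, G))
      last["g_loss"] <- g_loss
      last["i_loss"] <- i_loss
      if (!all(is.finite(c(last["c_loss"], g_loss))))
        stop("non-finite loss at epoch ", epoch, ", step ", step,
             " (critic ", last["c_loss"], ", generator ", g_loss, ")")
    }
    log_rows[[epoch]] <- data.frame(epoch = epoch,
                                    critic_loss = last[["c_loss"]],
                                    gen_loss = last[["g_loss"]],
                                    ident_loss = last[["i_loss"]])
  }
  structure(list(generator = gen, critic = cri, config = config, weights = w,
                 colmap_digest = original$colmap,
                 training_log = do.call(rbind, log_rows)),
            class = "generator_bundle")
}

#' @export
print.generator_bundle <- function(x, ...) {
  cat("generator_bundle: d =", x$generator$sizes[length(x$generator$sizes)],
      "; epochs =", x$config$epochs, "; lambda =", x$config$lambda,
      "; beta =", x$config$beta, "\n")
  invisible(x)
}

# Repair raw generator output into a valid encoded record: resolve each
# one-hot block to its argmax category, threshold missing-value indicators at
# 0.5, and apply the missing sentinel (value 0) where the indicator fires.
repair_encoded <- function(m, colmap) {
  for (v in unique(colmap$variable)) {
    rows <- colmap[colmap$variable == v, ]
    oh <- rows$col[rows$role == "onehot"]
    if (length(oh)) {
      block <- m[, oh, drop = FALSE]
      hard <- matrix(0, nrow(m), length(oh))
      hard[cbind(seq_len(nrow(m)), max.col(block, ties.method = "first"))] <- 1
      m[, oh] <- hard
    }
    ic <- rows$col[rows$role == "indicator"]
    if (length(ic)) {
      ind <- as.numeric(m[, ic] >= 0.5)
      m[, ic] <- ind
      vc <- rows$col[rows$role == "value"]
      if (length(vc)) m[ind == 1, vc] <- 0
    }
  }
  m
}

#' Generate a synthetic cohort from a trained bundle
#'
#' Produces one synthetic record `xhat_i = G(x_i, z_i)` per original record
#' (one fresh Gaussian `z` per patient), then repairs validity: every one-hot
#' block — including the treatment block, so each synthetic patient carries
#' exactly one treatment — is resolved by argmax, and missing-value
#' indicators are thresholded at 0.5 with the sentinel applied. Conditioning
#' on the original records preserves the treatment assignment mechanism.
#'
#' @param bundle A `generator_bundle` from [train_adsgan()].
#' @param original The `encoded_matrix` the bundle was trained on (same
#'   colmap).
#' @param seed RNG seed for the noise draw.
#' @return A synthetic `encoded_matrix` with N rows.
#' @export
generate_synthetic <- function(bundle, original, seed = 1) {
  stopifnot(inherits(bundle, "generator_bundle"),
            inherits(original, "encoded_matrix"))
  if (!identical(dim(bundle$colmap_digest), dim(original$colmap)) ||
      !identical(bundle$colmap_digest$variable, original$colmap$variable))
    stop("colmap mismatch: bundle was trained on a different encoding")
  X <- original$data
  set.seed(seed)
  Z <- matrix(stats::rnorm(nrow(X) * bundle$config$noise_dim), nrow(X))
  raw <- generator_apply(bundle$generator, X, Z)
  m <- repair_encoded(raw, original$colmap)
  colnames(m) <- colnames(X)
  encoded_matrix(m, original)
}
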