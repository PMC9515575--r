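# Minimal multilayer-perceptron engine: forward pass, reverse-mode gradients
# (parameters and inputs), reverse-over-reverse gradients for the WGAN-GP
# gradient penalty, and an Adam optimizer. Everything is seeded through R's
# RNG; all state is plain matrices so that trained models serialize as text.

#' Create a multilayer perceptron
#'
#' Builds a fully connected network with the given hidden widths. Hidden
#' activation is `tanh` (smooth, required for gradient-penalty training) or
#' `relu`; the output is `linear` or `sigmoid` (bounded to `[0,1]`). Weights
#' are initialized from the current RNG state (Glorot-style scaling), so
#' wrap construction in `set.seed()` for reproducibility.
#'
#' @param d_in,d_out Input and output dimensions.
#' @param hidden Integer vector of hidden-layer widths (may be empty for a
#'   linear map).
#' @param act Hidden activation, `"tanh"` or `"relu"`.
#' @param out_act Output activation, `"linear"` or `"sigmoid"`.
#' @return An object of class `sc_mlp`.
#' @export
mlp_new <- function(d_in, hidden, d_out, act = "tanh", out_act = "linear") {
  act <- match.arg(act, c("tanh", "relu"))
  out_act <- match.arg(out_act, c("linear", "sigmoid"))
  sizes <- c(d_in, hidden, d_out)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    fan_in <- sizes[l]
    sd <- if (act == "relu") sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(stats::rnorm(sizes[l + 1] * fan_in, sd = sd),
                     nrow = sizes[l + 1], ncol = fan_in)
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes, L = L, act = act,
                 out_act = out_act),
            class = "sc_mlp")
}

act_fun <- function(z, kind) switch(kind, tanh = tanh(z), relu = pmax(z, 0),
                                    linear = z, sigmoid = 1 / (1 + exp(-z)))
act_deriv <- function(z, a, kind) switch(kind,
  tanh = 1 - a^2, relu = (z > 0) * 1, linear = matrix(1, nrow(z), ncol(z)),
  sigmoid = a * (1 - a))

layer_kind <- function(net, l) if (l == net$L) net$out_act else net$act

#' Forward pass through an `sc_mlp`
#'
#' @param net An `sc_mlp`.
#' @param X n x d_in matrix.
#' @param dropout_rate Probability of dropping each hidden unit (inverted
#'   dropout; masks drawn from the current RNG). 0 disables.
#' @return List with `out` (n x d_out), and caches `A`, `Z`, `masks` for
#'   [mlp_backward()].
#' @export
mlp_forward <- function(net, X, dropout_rate = 0) {
  n <- nrow(X)
  A <- vector("list", net$L + 1L); Z <- vector("list", net$L)
  masks <- vector("list", net$L)
  A[[1]] <- X
  for (l in seq_len(net$L)) {
    Z[[l]] <- A[[l]] %*% t(net$W[[l]]) +
      matrix(net$b[[l]], n, length(net$b[[l]]), byrow = TRUE)
    A[[l + 1]] <- act_fun(Z[[l]], layer_kind(net, l))
    if (dropout_rate > 0 && l < net$L) {
      masks[[l]] <- matrix(stats::rbinom(length(Z[[l]]), 1, 1 - dropout_rate),
                           n) / (1 - dropout_rate)
      A[[l + 1]] <- A[[l + 1]] * masks[[l]]
    }
  }
  list(out = A[[net$L + 1L]], A = A, Z = Z, masks = masks)
}

#' Reverse-mode gradients of an `sc_mlp`
#'
#' Backpropagates the adjoint `dOut` of the network output, returning
#' parameter gradients and the gradient with respect to the input batch.
#'
#' @param net An `sc_mlp`.
#' @param fw Cache from [mlp_forward()].
#' @param dOut n x d_out adjoint matrix.
#' @return List with `dW`, `db` (parameter gradients) and `dX`.
#' @export
mlp_backward <- function(net, fw, dOut) {
  dW <- vector("list", net$L); db <- vector("list", net$L)
  dA <- dOut
  for (l in rev(seq_len(net$L))) {
    if (!is.null(fw$masks[[l]])) dA <- dA * fw$masks[[l]]
    dZ <- dA * act_deriv(fw$Z[[l]], act_fun(fw$Z[[l]], layer_kind(net, l)),
                         layer_kind(net, l))
    dW[[l]] <- t(dZ) %*% fw$A[[l]]
    db[[l]] <- colSums(dZ)
    dA <- dZ %*% net$W[[l]]
  }
  list(dW = dW, db = db, dX = dA)
}

#' Gradient of a scalar-output network with respect to its inputs
#'
#' @param net An `sc_mlp` with `d_out = 1`.
#' @param X n x d_in matrix.
#' @return n x d_in matrix of per-sample input gradients.
#' @export
mlp_input_grad <- function(net, X) {
  stopifnot(net$sizes[length(net$sizes)] == 1L)
  fw <- mlp_forward(net, X)
  mlp_backward(net, fw, matrix(1, nrow(X), 1))$dX
}

# Gradient penalty and its parameter gradients for a scalar-output smooth
# (tanh/linear) critic, by reverse-mode differentiation through the
# input-gradient computation itself (reverse-over-reverse). Returns the
# penalty mean((||grad_x D|| - 1)^2), the per-sample gradient norms, and
# dW/db = parameter gradients of the penalty.
mlp_gp_grads <- function(net, X) {
  if (net$act == "relu" && net$L > 1L)
    stop("gradient-penalty training requires a smooth (tanh) critic")
  n <- nrow(X); L <- net$L
  fw <- mlp_forward(net, X)
  # first reverse sweep: S[[l]] = adjoint of Z_l for the scalar output,
  # Delta[[l]] = adjoint of A_l; input gradient G = Delta[[0]]
  S <- vector("list", L); Delta <- vector("list", L + 1L)
  Delta[[L + 1L]] <- matrix(1, n, 1)
  sp <- vector("list", L)   # sigma'(Z_l)
  spp <- vector("list", L)  # sigma''(Z_l)
  for (l in rev(seq_len(L))) {
    kind <- layer_kind(net, l)
    a <- fw$A[[l + 1L]]
    sp[[l]] <- act_deriv(fw$Z[[l]], a, kind)
    spp[[l]] <- switch(kind, tanh = -2 * a * (1 - a^2),
                       linear = matrix(0, n, ncol(a)),
                       sigmoid = a * (1 - a) * (1 - 2 * a),
                       relu = matrix(0, n, ncol(a)))
    S[[l]] <- Delta[[l + 1L]] * sp[[l]]
    Delta[[l]] <- S[[l]] %*% net$W[[l]]
  }
  G <- Delta[[1L]]
  norms <- sqrt(rowSums(G^2))
  penalty <- mean((norms - 1)^2)
  # seed for the second sweep: d penalty / d G
  scale <- ifelse(norms > 1e-12, 2 * (norms - 1) / norms / n, 0)
  V <- G * scale
  # second sweep, walking the first reverse sweep in forward order
  dW <- lapply(net$W, function(w) w * 0)
  db <- lapply(net$b, function(bb) bb * 0)
  Zhat <- vector("list", L)  # adjoint contributions to Z_l via sigma'(Z_l)
  Dhat <- V                  # adjoint of Delta[[l]] entering layer l
  for (l in seq_len(L)) {
    Shat <- Dhat %*% t(net$W[[l]])        # adjoint of S[[l]]
    dW[[l]] <- dW[[l]] + t(S[[l]]) %*% Dhat
    Zhat[[l]] <- Shat * Delta[[l + 1L]] * spp[[l]]
    Dhat <- Shat * sp[[l]]                # adjoint of Delta[[l+1]]
  }
  # backprop the Zhat contributions through the primal forward pass
  dA <- matrix(0, n, ncol(fw$A[[L + 1L]]))
  for (l in rev(seq_len(L))) {
    dZ <- Zhat[[l]] + dA * sp[[l]]
    dW[[l]] <- dW[[l]] + t(dZ) %*% fw$A[[l]]
    db[[l]] <- db[[l]] + colSums(dZ)
    dA <- dZ %*% net$W[[l]]
  }
  list(penalty = penalty, norms = norms, dW = dW, db = db)
}

# ---- Adam -------------------------------------------------------------------

adam_new <- function(net) {
  zeros <- function(x) lapply(x, function(p) p * 0)
  list(mW = zeros(net$W), vW = zeros(net$W),
       mb = zeros(net$b), vb = zeros(net$b), t = 0L)
}

# One Adam update; `maximize` flips to gradient ascent. Returns list(net, opt).
adam_step <- function(net, opt, dW, db, lr, beta1 = 0.5, beta2 = 0.9,
                      eps = 1e-8, maximize = FALSE) {
  opt$t <- opt$t + 1L
  sgn <- if (maximize) -1 else 1
  c1 <- 1 - beta1^opt$t; c2 <- 1 - beta2^opt$t
  for (l in seq_along(net$W)) {
    gW <- sgn * dW[[l]]; gb <- sgn * db[[l]]
    opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * gW
    opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * gW^2
    opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * gb
    opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * gb^2
    net$W[[l]] <- net$W[[l]] -
      lr * (opt$mW[[l]] / c1) / (sqrt(opt$vW[[l]] / c2) + eps)
    net$b[[l]] <- net$b[[l]] -
      lr * (opt$mb[[l]] / c1) / (sqrt(opt$vb[[l]] / c2) + eps)
  }
  list(net = net, opt = opt)
}

sum_grads <- function(...) {
  gs <- list(...)
  out <- gs[[1]]
  for (g in gs[-1]) for (l in seq_along(out)) out[[l]] <- out[[l]] + g[[l]]
  out
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
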