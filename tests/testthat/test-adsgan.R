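test_that("critic loss matches analytic values for constant and linear critics", {
  real <- matrix(runif(8), 4); fake <- matrix(runif(8), 4)
  # constant critic: Wasserstein term 0, gradient 0 => penalty (0-1)^2 = 1
  const <- linear_critic(c(0, 0), c_ = 3)
  expect_equal(critic_loss(real, fake, const, mu = 10), -10)
  # linear critic with |a| = 1: unit gradient everywhere => penalty 0
  a <- c(0.6, 0.8)
  lin <- linear_critic(a)
  expected <- mean(real %*% a) - mean(fake %*% a)
  expect_equal(critic_loss(real, fake, lin, mu = 10), expected)
})

test_that("critic loss equals a hand-computed value on a fixed 4-point fixture", {
  real <- rbind(c(0.1, 0.2), c(0.4, 0.4), c(0.9, 0.1), c(0.3, 0.8))
  fake <- rbind(c(0.2, 0.2), c(0.5, 0.5), c(0.1, 0.1), c(0.8, 0.8))
  a <- c(2, -1); c_ <- 0.5
  cri <- linear_critic(a, c_)
  u <- c(0.25, 0.5, 0.75, 1)
  # by hand: E D(x) - E D(xhat) - mu * (||a|| - 1)^2 (gradient is a
  # everywhere so the interpolation points don't matter for a linear critic)
  lhs <- mean(real %*% a + c_) - mean(fake %*% a + c_) -
    10 * (sqrt(5) - 1)^2
  expect_equal(critic_loss(real, fake, cri, mu = 10, interp_u = u), lhs)
  expect_error(critic_loss(real, fake[, 1, drop = FALSE], cri),
               "width mismatch")
})

test_that("contrastive loss is the triplet hinge on the weighted distances", {
  w <- c(1, 1)
  x <- matrix(c(0, 0), 1)
  z <- matrix(0, 1, 1)
  # generator stub returning a fixed point
  gen_at <- function(p) function(X, Z) matrix(p, nrow(X), length(p),
                                              byrow = TRUE)
  # x' = x: both distances equal, hinge 0
  expect_equal(contrastive_loss(x, x, z, gen_at(c(3, 4)), w), 0)
  # U(x,G)=2 < U(x',G)=5: hinge inactive
  xp <- matrix(c(0, 7), 1)
  expect_equal(contrastive_loss(x, xp, z, gen_at(c(0, 2)), w), 0)
  # U(x,G)=5 > U(x',G)=2: hinge active, 5 - 2 = 3
  xp <- matrix(c(0, 7), 1)
  expect_equal(contrastive_loss(x, xp, z, gen_at(c(0, 5)), w), 3)
})

test_that("identifiability loss is 0 for the identity generator and drops the hinge at beta=0", {
  set.seed(3)
  X <- matrix(runif(12), 4)
  Xn <- X[c(2, 3, 4, 1), ]
  Z <- matrix(rnorm(4), 4)
  w <- rep(1, 3)
  ident <- function(X, Z) X
  expect_equal(identifiability_loss(X, Xn, Z, ident, w), 0)
  # fixed affine generator, hand-computed termwise
  gen <- function(X, Z) 0.5 * X + 0.1
  G <- 0.5 * X + 0.1
  u_a <- sqrt(rowSums((X - G)^2))
  u_n <- sqrt(rowSums((Xn - G)^2))
  expect_equal(identifiability_loss(X, Xn, Z, gen, w, beta = 0),
               mean(-u_a))
  expect_equal(identifiability_loss(X, Xn, Z, gen, w, beta = 2),
               mean(-u_a) + 2 * mean(pmax(0, u_a - u_n)))
})

test_that("training is seeded-deterministic end to end", {
  fx <- small_fixture(n = 150, arms = 3, seed = 5)
  em <- encode(fx$cohort)
  cfg <- gan_config(epochs = 1, batch_size = 32, noise_dim = 4,
                    gen_layers = c(16), critic_layers = c(16), seed = 9)
  b1 <- train_adsgan(em, cfg)
  b2 <- train_adsgan(em, cfg)
  expect_identical(b1$generator$W, b2$generator$W)
  expect_identical(b1$training_log, b2$training_log)
  s1 <- generate_synthetic(b1, em, seed = 4)
  s2 <- generate_synthetic(b2, em, seed = 4)
  expect_identical(s1$data, s2$data)
})

test_that("generated output is a valid encoded matrix with one treatment per patient", {
  fx <- small_fixture(n = 150, arms = 3, seed = 6)
  em <- encode(fx$cohort)
  b <- train_adsgan(em, gan_config(epochs = 1, batch_size = 32,
                                   noise_dim = 4, gen_layers = c(16),
                                   critic_layers = c(16), seed = 2))
  syn <- generate_synthetic(b, em, seed = 3)
  expect_identical(dim(syn$data), dim(em$data))
  expect_true(all(syn$data >= 0 & syn$data <= 1))
  part <- partition(em)
  tb <- syn$data[, part$treatment_cols]
  expect_true(all(rowSums(tb) == 1))
  expect_true(all(tb %in% c(0, 1)))
  # epsilon of the output against the original is finite and in [0,1]
  eps <- epsilon_identifiability(em, syn)$epsilon
  expect_gte(eps, 0); expect_lte(eps, 1)
  # a fresh matrix with a different colmap is rejected
  other <- encode(toy_cohort())
  expect_error(generate_synthetic(b, other, seed = 1), "colmap")
})

test_that("desk-scale training moves the generator toward the data (smoke)", {
  fx <- small_fixture(n = 400, arms = 3, seed = 8)
  em <- encode(fx$cohort)
  cfg <- gan_config(epochs = 6, batch_size = 64, noise_dim = 8,
                    gen_layers = c(32, 32), critic_layers = c(32, 32),
                    lambda = 0.1, seed = 1)
  b <- train_adsgan(em, cfg)
  syn <- generate_synthetic(b, em, seed = 2)
  otc <- ot_config(subsample = 200, repeats = 2, seed = 3)
  w_syn <- wasserstein_estimate(em, syn, otc)
  set.seed(4)
  U <- matrix(runif(length(em$data)), nrow(em$data))
  w_unif <- wasserstein_estimate(em$data, U, otc)
  expect_lt(w_syn, w_unif)
})
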