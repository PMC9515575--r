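# Shared builders and independent oracles for the test suite. Oracles are
# deliberately written as plain loops, independent of the package's
# vectorized code paths.

toy_schema <- function() {
  cohort_schema(list(
    variable_spec("age", "continuous", range = c(20, 80)),
    variable_spec("drug", "categorical", categories = c("t0", "A", "B"),
                  role = "treatment"),
    variable_spec("sbp_pre", "continuous", range = c(100, 200),
                  role = "pre_lab"),
    variable_spec("sbp_post", "continuous", range = c(80, 220),
                  role = "post_lab"),
    variable_spec("ldl", "continuous", range = c(0, 300),
                  missingness_allowed = TRUE)))
}

toy_cohort <- function(ldl = c(120, NA, 180)) {
  cohort_table(data.frame(age = c(20, 50, 80),
                          drug = c("t0", "A", "B"),
                          sbp_pre = c(150, 160, 140),
                          sbp_post = c(138, 150, 145),
                          ldl = ldl,
                          stringsAsFactors = FALSE),
               toy_schema())
}

small_fixture <- function(n = 400, arms = 4, seed = 1, ...) {
  simulate_cohort(fixture_config(n = n, n_treatments = arms, seed = seed,
                                 true_effects = seq(0, -9,
                                                    length.out = arms), ...))
}

# independent epsilon oracle: plain double loops, no shared code
oracle_epsilon <- function(A, B, wv) {
  n <- nrow(A)
  r <- rep(Inf, n); r_hat <- rep(Inf, n)
  for (i in 1:n) {
    for (j in 1:n) if (j != i) {
      u <- sqrt(sum((wv * (A[i, ] - A[j, ]))^2))
      if (u < r[i]) r[i] <- u
    }
    for (j in 1:nrow(B)) {
      u <- sqrt(sum((wv * (A[i, ] - B[j, ]))^2))
      if (u < r_hat[i]) r_hat[i] <- u
    }
  }
  list(epsilon = mean(r > r_hat), r = r, r_hat = r_hat)
}

# brute-force assignment oracle: enumerate all permutations (n <= 6)
perms <- function(v) {
  if (length(v) <= 1) return(matrix(v, nrow = 1))
  out <- NULL
  for (i in seq_along(v))
    out <- rbind(out, cbind(v[i], perms(v[-i])))
  out
}

oracle_assignment_cost <- function(cost) {
  p <- perms(seq_len(nrow(cost)))
  best <- Inf
  for (k in seq_len(nrow(p))) {
    tot <- sum(cost[cbind(seq_len(nrow(cost)), p[k, ])])
    if (tot < best) best <- tot
  }
  best
}

# a linear critic D(x) = a . x + c as an sc_mlp
linear_critic <- function(a, c_ = 0) {
  net <- mlp_new(length(a), integer(0), 1)
  net$W[[1]] <- matrix(a, nrow = 1)
  net$b[[1]] <- c_
  net
}
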