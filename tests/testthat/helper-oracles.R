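# Independent brute-force oracles, written as plain scalar loops so they
# share no code path with the vectorized implementations they check.

naive_entropy <- function(p) {
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) total <- total - p[i] * log(p[i])
  }
  total
}

naive_kl <- function(p, q) {
  total <- 0
  for (i in seq_along(p)) {
    if (p[i] > 0) total <- total + p[i] * log(p[i] / q[i])
  }
  total
}

# I(X;Y) by the definitional double sum over the joint
naive_mi <- function(m) {
  px <- rowSums(m)
  py <- colSums(m)
  total <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if (m[i, j] > 0) {
        total <- total + m[i, j] * log(m[i, j] / (px[i] * py[j]))
      }
    }
  }
  total
}

# random joint distribution of the given shape (uses the ambient RNG state)
random_joint_matrix <- function(nx, ny) {
  m <- matrix(stats::rexp(nx * ny), nx, ny)
  m / sum(m)
}

random_simplex <- function(k) {
  g <- stats::rexp(k)
  g / sum(g)
}

random_simplex_seeded <- function(k, seed) {
  withr::with_seed(seed, random_simplex(k))
}

# final-state distribution of an open-loop policy by exhaustive path
# enumeration: sum over all state paths of q0(s0) * prod transitions
path_sum_final_state <- function(gm, q0, policy) {
  n <- gm$n_states
  depth <- length(policy)
  paths <- as.matrix(do.call(expand.grid, rep(list(seq_len(n)), depth + 1)))
  out <- numeric(n)
  for (r in seq_len(nrow(paths))) {
    p <- q0[paths[r, 1]]
    if (p == 0) next
    for (t in seq_len(depth)) {
      p <- p * gm$transitions[paths[r, t + 1], paths[r, t], policy[t]]
      if (p == 0) break
    }
    out[paths[r, depth + 1]] <- out[paths[r, depth + 1]] + p
  }
  out
}

# standard small random fixture used across active-inference tests
fixture_model <- function(seed, n_states = 3, n_obs = 4, n_controls = 2,
                          concentration = 1) {
  make_random_model(n_states, n_obs, n_controls,
                    concentration = concentration, seed = seed)
}

expect_near <- function(object, expected, tol = 1e-10) {
  expect_true(all(abs(object - expected) < tol),
              label = sprintf("max|diff| = %.3g", max(abs(object - expected))))
}
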