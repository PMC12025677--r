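# 2-state, 2-action MDP with seeded random stochastic dynamics
random_chain <- function(seed) {
  withr::with_seed(seed, {
    Tr <- array(0, c(2, 2, 2))
    for (a in 1:2) for (s in 1:2) {
      p <- stats::runif(1, 0.1, 0.9)
      Tr[, s, a] <- c(p, 1 - p)
    }
    mdp_spec(Tr)
  })
}

test_that("trajectory reward matches hand-computed closed forms", {
  # deterministic everything: all logs zero
  Tr <- array(0, c(2, 2, 1)); Tr[2, 1, 1] <- 1; Tr[1, 2, 1] <- 1
  mdp <- mdp_spec(Tr)
  pol <- state_policy(matrix(1, 2, 1))
  expect_equal(mop_reward(c(1, 2, 1, 2), c(1, 1, 1), pol, mdp,
                          mop_params(1, 0.3, 0.5)), 0)
  # uniform policy over 2 actions, deterministic transitions, 4 steps
  Tr2 <- array(0, c(2, 2, 2))
  Tr2[2, 1, ] <- 1; Tr2[1, 2, ] <- 1
  mdp2 <- mdp_spec(Tr2)
  pol2 <- uniform_policy(mdp2)
  r <- mop_reward(c(1, 2, 1, 2, 1), c(1, 2, 1, 2), pol2, mdp2,
                  mop_params(alpha = 1, beta = 7, gamma = 0.5))
  expect_equal(r, log(2) * (1 + 0.5 + 0.25 + 0.125), tolerance = 1e-10)
  expect_equal(r, 1.299651, tolerance = 1e-6)
  # alpha = 0, beta = 1: a single step with transition probability 1/4
  Tr3 <- array(0, c(2, 2, 1)); Tr3[, 1, 1] <- c(0.75, 0.25); Tr3[2, 2, 1] <- 1
  mdp3 <- mdp_spec(Tr3)
  pol3 <- state_policy(matrix(1, 2, 1))
  expect_equal(mop_reward(c(1, 2), 1, pol3, mdp3, mop_params(0, 1, 0.9)),
               log(4), tolerance = 1e-12)
  # zero-probability step is an explicit error
  expect_error(mop_reward(c(2, 1), 1, pol3, mdp3, mop_params(0, 1, 0.9)),
               "zero probability")
})

test_that("policy evaluation matches geometric closed forms", {
  # single state, n self-loop actions, uniform policy
  for (n in c(2, 3, 5)) {
    Tr <- array(0, c(1, 1, n)); Tr[1, 1, ] <- 1
    mdp <- mdp_spec(Tr)
    V <- mop_value(mdp, uniform_policy(mdp), mop_params(1, 0, 0.9))
    expect_equal(V, 10 * log(n), tolerance = 1e-8)
  }
  # absorbing state evaluates to exactly zero
  Tr <- array(0, c(2, 2, 2))
  Tr[1, 1, ] <- 1                 # state 1 absorbing
  Tr[, 2, 1] <- c(0.5, 0.5); Tr[2, 2, 2] <- 1
  mdp <- mdp_spec(Tr, absorbing = 1)
  V <- mop_value(mdp, uniform_policy(mdp), mop_params(1, 0.5, 0.9))
  expect_identical(V[1], 0)
  expect_gt(V[2], 0)
})

test_that("policy evaluation agrees with a Monte-Carlo estimate of the value", {
  mdp <- random_chain(61)
  pol <- state_policy(withr::with_seed(610, {
    t(vapply(1:2, function(s) random_simplex(2), numeric(2)))
  }))
  params <- mop_params(alpha = 0.8, beta = 0.5, gamma = 0.9)
  V <- mop_value(mdp, pol, params)
  # vectorised Monte Carlo: M episodes, horizon long enough that the
  # truncated tail is far below the Monte-Carlo noise floor
  M <- 4000L; L <- 250L
  withr::with_seed(611, {
    s <- rep(1L, M)
    total <- numeric(M)
    disc <- 1
    for (t in seq_len(L)) {
      a <- 1L + (stats::runif(M) > pol[cbind(s, 1)])
      p_next1 <- mdp$transitions[cbind(1L, s, a)]
      s_next <- 1L + (stats::runif(M) > p_next1)
      pr_a <- pol[cbind(s, a)]
      pr_s <- mdp$transitions[cbind(s_next, s, a)]
      total <- total - disc * (params$alpha * log(pr_a) + params$beta * log(pr_s))
      disc <- disc * params$gamma
      s <- s_next
    }
    se <- stats::sd(total) / sqrt(M)
    expect_lt(abs(mean(total) - V[1]), 3 * se)
  })
})

test_that("soft value iteration recovers symmetric closed forms", {
  # single state, n self-loop actions, beta = 0: uniform policy, V = alpha log n / (1 - gamma)
  for (n in c(2, 4)) {
    Tr <- array(0, c(1, 1, n)); Tr[1, 1, ] <- 1
    mdp <- mdp_spec(Tr)
    for (alpha in c(0.5, 1, 2)) {
      fit <- mop_optimize(mdp, mop_params(alpha, 0, 0.9))
      expect_near(as.numeric(fit$policy), rep(1 / n, n), 1e-9)
      expect_equal(fit$value, alpha * log(n) / 0.1, tolerance = 1e-7)
    }
  }
  # two actions with identical dynamics split 50/50
  mdp2 <- random_chain(62)
  Tr_dup <- mdp2$transitions
  Tr_dup[, , 2] <- Tr_dup[, , 1]
  fit2 <- mop_optimize(mdp_spec(Tr_dup), mop_params(1, 0.4, 0.9))
  expect_near(unclass(fit2$policy), 0.5, 1e-9)
})

test_that("returned policy and value are self-consistent under re-evaluation", {
  set.seed(63)
  for (i in 1:5) {
    Tr <- array(0, c(3, 3, 2))
    for (a in 1:2) for (s in 1:3) Tr[, s, a] <- random_simplex(3)
    mdp <- mdp_spec(Tr)
    params <- mop_params(stats::runif(1, 0.5, 2), stats::runif(1, -1, 1), 0.9)
    tol <- 1e-10
    fit <- mop_optimize(mdp, params, tol = tol)
    V_re <- mop_value(mdp, fit$policy, params, tol = tol)
    expect_near(fit$value, V_re, 1e-7)
  }
})

test_that("the soft Bellman operator contracts at rate gamma", {
  mdp <- random_chain(64)
  fit <- mop_optimize(mdp, mop_params(1, 0.3, 0.9))
  tr <- fit$change_trace
  # ignore iterates at the numerical noise floor near the fixed point
  keep <- tr[-length(tr)] > 1e-8
  ratios <- (tr[-1] / tr[-length(tr)])[keep]
  expect_true(all(ratios <= 0.9 + 1e-4))
})

test_that("soft value iteration avoids absorbing states more than uniform", {
  # 3-state toy: from state 1, action 1 -> state 2 (live loop),
  # action 2 -> state 3 (absorbing); state 2 returns to 1 either way
  Tr <- array(0, c(3, 3, 2))
  Tr[2, 1, 1] <- 1; Tr[3, 1, 2] <- 1
  Tr[1, 2, ] <- 1
  Tr[3, 3, ] <- 1
  mdp <- mdp_spec(Tr, absorbing = 3)
  params <- mop_params(1, 0, 0.9)
  fit <- mop_optimize(mdp, params)
  p_enter <- fit$policy[1, 2]
  expect_lt(p_enter, 0.5) # strictly less than the uniform baseline
  # exhaustive policy grid search at resolution 0.01 over pi(a1|s1)
  grid <- seq(0, 1, by = 0.01)
  vals <- vapply(grid, function(p) {
    if (p %in% c(0, 1)) return(-Inf) # degenerate rows break log; optimum is interior
    pol <- state_policy(rbind(c(p, 1 - p), c(0.5, 0.5), c(1, 0)))
    mop_value(mdp, pol, params)[1]
  }, numeric(1))
  p_star <- grid[which.max(vals)]
  expect_equal(fit$policy[1, 1], p_star, tolerance = 0.01)
  expect_gt(p_star, 0.5)
})

test_that("negative beta shifts weight onto the deterministic action", {
  # symmetric 2-state MDP: action 1 deterministic self-loop, action 2 noisy
  Tr <- array(0, c(2, 2, 2))
  Tr[1, 1, 1] <- 1; Tr[2, 2, 1] <- 1       # deterministic stay
  Tr[, 1, 2] <- c(0.5, 0.5); Tr[, 2, 2] <- c(0.5, 0.5) # noisy
  mdp <- mdp_spec(Tr)
  p_det <- vapply(c(0, -0.5, -1), function(b) {
    mop_optimize(mdp, mop_params(1, b, 0.9))$policy[1, 1]
  }, numeric(1))
  expect_equal(p_det[1], 0.5, tolerance = 1e-8)
  expect_true(all(diff(p_det) > 0))
})

test_that("simulation is deterministic under a seed and hits stationarity", {
  Tr <- array(0, c(2, 2, 2))
  Tr[, 1, 1] <- c(0.5, 0.5); Tr[, 1, 2] <- c(0.5, 0.5)
  Tr[, 2, 1] <- c(0.5, 0.5); Tr[, 2, 2] <- c(0.5, 0.5)
  mdp <- mdp_spec(Tr)
  pol <- uniform_policy(mdp)
  t1 <- simulate_trajectory(mdp, pol, 1000, seed = 9)
  t2 <- simulate_trajectory(mdp, pol, 1000, seed = 9)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$actions, t2$actions)
  # symmetric chain: empirical visits near (0.5, 0.5)
  t3 <- simulate_trajectory(mdp, pol, 100000, seed = 10)
  expect_near(t3$visit_distribution, 0.5, 0.01)
  # deterministic everything: the unique orbit
  Trd <- array(0, c(2, 2, 1)); Trd[2, 1, 1] <- 1; Trd[1, 2, 1] <- 1
  td <- simulate_trajectory(mdp_spec(Trd), state_policy(matrix(1, 2, 1)),
                            4, seed = 1, start = 1)
  expect_equal(td$states, c(1L, 2L, 1L, 2L, 1L))
})

test_that("parameter validation enforces the documented domains", {
  expect_error(mop_params(-1, 0, 0.9), "non-negative")
  expect_error(mop_params(0, 0, 0.9), "beta")
  expect_error(mop_params(1, 0, 1), "gamma")
  Tr <- array(0, c(1, 1, 2)); Tr[1, 1, ] <- 1
  expect_error(mop_optimize(mdp_spec(Tr), mop_params(0, 1, 0.9)), "alpha > 0")
})

test_that("mop fit tidiers expose policy rows and value", {
  mdp <- random_chain(65)
  fit <- mop_optimize(mdp, mop_params(1, 0, 0.9))
  td <- tidy(fit)
  expect_equal(nrow(td), 4)
  sums <- tapply(td$probability, td$state, sum)
  expect_near(as.numeric(sums), 1, 1e-9)
  expect_equal(glance(fit)$gamma, 0.9)
})
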