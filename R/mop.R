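#' Maximum-occupancy parameters
#'
#' Weights of the occupancy reward: `alpha` scales action-path entropy,
#' `beta` scales state-path (transition) entropy, `gamma` is the usual
#' temporal discount. `beta` may be negative, in which case the agent
#' prefers predictable transitions while still diversifying its actions - a
#' regime that approximates empowerment's controllability preference.
#' Defaults alpha = 1, beta = 0 mirror the setting used in the occupancy
#' literature's reference experiments (action entropy only).
#'
#' @param alpha non-negative action-entropy weight; `alpha = 0` is allowed
#'   only with `beta != 0` (otherwise the reward is identically zero).
#' @param beta real state-entropy weight (negative allowed).
#' @param gamma discount in `[0, 1)`.
#' @return An object of class `imotiv_mop_params`.
#' @export
mop_params <- function(alpha = 1, beta = 0, gamma = 0.99) {
  if (alpha < 0) abort("'alpha' must be non-negative")
  if (alpha == 0 && beta == 0) abort("alpha = 0 requires beta != 0 (reward would be identically zero)")
  if (gamma < 0 || gamma >= 1) abort("'gamma' must be in [0, 1)")
  structure(list(alpha = alpha, beta = beta, gamma = gamma),
            class = "imotiv_mop_params")
}

# per-(s, a) next-state transition entropy H(S'|s, a), n_states x n_actions
transition_entropy <- function(mdp) {
  matrix(vapply(seq_len(mdp$n_actions), function(a) {
    vapply(seq_len(mdp$n_states), function(s) {
      -sum(xlogx(mdp$transitions[, s, a]))
    }, numeric(1))
  }, numeric(mdp$n_states)), nrow = mdp$n_states)
}

#' State-conditional stochastic policy
#'
#' @param matrix numeric matrix `n_states x n_actions`, each row a
#'   distribution over actions (validated and renormalised).
#' @return An object of class `imotiv_state_policy`.
#' @export
state_policy <- function(matrix) {
  m <- as.matrix(matrix)
  for (s in seq_len(nrow(m))) {
    stop_not_prob(m[s, ], sprintf("policy row (state %d)", s))
    m[s, ] <- m[s, ] / sum(m[s, ])
  }
  structure(m, class = "imotiv_state_policy")
}

#' Uniform state policy for an MDP
#'
#' @param mdp an [mdp_spec()].
#' @return A [state_policy()] assigning equal probability to every action in
#'   every state.
#' @export
uniform_policy <- function(mdp) {
  state_policy(matrix(1 / mdp$n_actions, mdp$n_states, mdp$n_actions))
}

#' Occupancy reward of a realised trajectory
#'
#' R(tau) = -sum over steps t of gamma^t * (alpha log pi(a(t)|s(t)) +
#' beta log P(s(t+1)|s(t),a(t))), the discounted surprisal of the realised
#' action-state path (t starts at 0 on the first step). High-entropy
#' (improbable) actions and transitions earn high reward.
#'
#' @param states integer vector of visited states, length n+1.
#' @param actions integer vector of taken actions, length n.
#' @param policy a [state_policy()].
#' @param mdp an [mdp_spec()].
#' @param params [mop_params()].
#' @return Scalar reward in nats.
#' @export
mop_reward <- function(states, actions, policy, mdp, params) {
  if (length(states) != length(actions) + 1) {
    abort("'states' must be one longer than 'actions'")
  }
  n <- length(actions)
  if (n == 0) return(0)
  pi_p <- vapply(seq_len(n), function(t) policy[states[t], actions[t]],
                 numeric(1))
  tr_p <- vapply(seq_len(n), function(t) {
    mdp$transitions[states[t + 1], states[t], actions[t]]
  }, numeric(1))
  if (any(pi_p == 0) || any(tr_p == 0)) {
    t_bad <- which(pi_p == 0 | tr_p == 0)[1]
    abort(sprintf("trajectory step t=%d has zero probability under the policy/dynamics (log of zero)",
                  t_bad - 1))
  }
  disc <- params$gamma^(seq_len(n) - 1)
  -sum(disc * (params$alpha * log(pi_p) + params$beta * log(tr_p)))
}

#' Occupancy value of a policy (policy evaluation)
#'
#' Evaluates V(s) = the expected discounted sum of alpha H(A|s(t)) + beta H(S(t+1)|s(t),a(t))
#' by iterating the linear Bellman fixed-point equation
#' V(s) <- sum_a pi(a|s) ( -alpha log pi(a|s) + beta H(S'|s,a) +
#' gamma sum_s' P(s'|s,a) V(s') )
#' to convergence. For gamma < 1 the operator is a gamma-contraction, so
#' convergence is geometric and unconditional. Absorbing states are pinned
#' to V = 0: they are modelled as having a single effective (self-loop)
#' action, hence zero action and transition entropy forever.
#'
#' @param mdp an [mdp_spec()].
#' @param policy a [state_policy()].
#' @param params [mop_params()].
#' @param tol sup-norm convergence tolerance in nats (default 1e-10).
#' @param max_iter safety cap (default 1e6; unreachable for moderate gamma).
#' @return Numeric vector of per-state values (nats).
#' @export
mop_value <- function(mdp, policy, params, tol = 1e-10, max_iter = 1e6) {
  stopifnot(inherits(mdp, "imotiv_mdp"))
  hs <- transition_entropy(mdp)
  # per-state expected immediate reward under the policy
  r <- vapply(seq_len(mdp$n_states), function(s) {
    p <- policy[s, ]
    sum(p * (params$beta * hs[s, ])) - params$alpha * sum(xlogx(p))
  }, numeric(1))
  r[mdp$absorbing] <- 0
  # policy-induced state transition matrix (rows: s, cols: s')
  P <- t(vapply(seq_len(mdp$n_states), function(s) {
    as.numeric(mdp$transitions[, s, ] %*% policy[s, ])
  }, numeric(mdp$n_states)))
  V <- numeric(mdp$n_states)
  for (iter in seq_len(max_iter)) {
    V_new <- r + params$gamma * as.numeric(P %*% V)
    V_new[mdp$absorbing] <- 0
    if (max(abs(V_new - V)) < tol) return(V_new)
    V <- V_new
  }
  abort("policy evaluation did not converge within max_iter (should be impossible for gamma < 1)")
}

#' Optimal maximum-occupancy policy by soft value iteration
#'
#' The alpha-weighted action-entropy term makes the per-state maximisation
#' over action distributions analytic: with
#' Q(s,a) = beta H(S'|s,a) + gamma sum_s' P(s'|s,a) V(s'),
#' the maximising policy is the Boltzmann distribution
#' pi*(a|s) proportional to exp(Q(s,a)/alpha) and the maximised value is the
#' log-partition V(s) = alpha log sum_a exp(Q(s,a)/alpha). Iterating this
#' soft Bellman operator is a gamma-contraction, so the fixed point is
#' unique and the returned policy evaluates back to the returned V.
#' Absorbing states are pinned to V = 0 with a point-mass policy on the
#' first action (their single effective action).
#'
#' @inheritParams mop_value
#' @return An object of class `imotiv_mop_fit`: list with `policy`
#'   (a [state_policy()]), `value` (per-state V, nats), `iterations`,
#'   `sup_change` (final sup-norm change), `change_trace` (sup-norm change
#'   per sweep, whose decay rate exhibits the gamma-contraction), and
#'   `params`.
#' @export
mop_optimize <- function(mdp, params, tol = 1e-10, max_iter = 1e6) {
  stopifnot(inherits(mdp, "imotiv_mdp"))
  if (params$alpha <= 0) {
    abort("soft value iteration requires alpha > 0; for alpha = 0 use plain value iteration (not provided)")
  }
  hs <- transition_entropy(mdp)
  V <- numeric(mdp$n_states)
  sup_change <- Inf
  change_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Q <- params$beta * hs +
      params$gamma * matrix(vapply(seq_len(mdp$n_actions), function(a) {
        as.numeric(crossprod(mdp$transitions[, , a], V))
      }, numeric(mdp$n_states)), nrow = mdp$n_states)
      V_new <- params$alpha * apply(Q / params$alpha, 1, logsumexp)
    V_new[mdp$absorbing] <- 0
    sup_change <- max(abs(V_new - V))
    change_trace <- c(change_trace, sup_change)
    V <- V_new
    if (sup_change < tol || iter >= max_iter) break
  }
  if (sup_change >= tol) {
    abort("soft value iteration did not converge within max_iter")
  }
  Q <- params$beta * hs +
    params$gamma * matrix(vapply(seq_len(mdp$n_actions), function(a) {
      as.numeric(crossprod(mdp$transitions[, , a], V))
    }, numeric(mdp$n_states)), nrow = mdp$n_states)
  pol <- t(apply(Q / params$alpha, 1, function(row) {
    exp(row - logsumexp(row))
  }))
  for (s in mdp$absorbing) {
    pol[s, ] <- 0
    pol[s, 1] <- 1
  }
  structure(
    list(policy = state_policy(pol), value = V, iterations = iter,
         sup_change = sup_change, change_trace = change_trace,
         params = params),
    class = "imotiv_mop_fit")
}

#' @export
print.imotiv_mop_fit <- function(x, ...) {
  cat(sprintf("<MOP fit: alpha=%g beta=%g gamma=%g, %d iterations>\n",
              x$params$alpha, x$params$beta, x$params$gamma, x$iterations))
  cat("value head:", paste(sprintf("%.4f", utils::head(x$value, 6)),
                           collapse = " "), "\n")
  invisible(x)
}

#' Simulate a trajectory under a state policy
#'
#' Alternately samples actions from the policy and next states from the
#' dynamics, starting from `start`. Fully reproducible under `seed`.
#'
#' @param mdp an [mdp_spec()].
#' @param policy a [state_policy()].
#' @param steps number of action steps.
#' @param seed integer seed.
#' @param start starting state index.
#' @param params optional [mop_params()]; if supplied the trajectory's
#'   occupancy reward is computed.
#' @return An object of class `imotiv_trajectory`: list with
#'   `states` (length `steps + 1`), `actions` (length `steps`),
#'   `reward` (nats, or `NA` when `params` is absent),
#'   `visit_distribution` (empirical distribution over states, counted over
#'   `states[1..steps]`), `visit_entropy` (nats), and
#'   `absorbing_frequency` (fraction of counted steps spent in absorbing
#'   states).
#' @export
simulate_trajectory <- function(mdp, policy, steps, seed, start = 1L,
                                params = NULL) {
  stopifnot(inherits(mdp, "imotiv_mdp"))
  if (start < 1 || start > mdp$n_states) abort("'start' out of range")
  withr::local_seed(seed)
  states <- integer(steps + 1L)
  actions <- integer(steps)
  states[1] <- as.integer(start)
  for (t in seq_len(steps)) {
    a <- sample.int(mdp$n_actions, 1, prob = policy[states[t], ])
    s_next <- sample.int(mdp$n_states, 1, prob = mdp$transitions[, states[t], a])
    actions[t] <- a
    states[t + 1L] <- s_next
  }
  visits <- tabulate(states[seq_len(steps)], nbins = mdp$n_states)
  visit_dist <- visits / steps
  reward <- if (is.null(params)) NA_real_ else {
    mop_reward(states, actions, policy, mdp, params)
  }
  structure(
    list(states = states, actions = actions, reward = reward,
         visit_distribution = visit_dist,
         visit_entropy = entropy(categorical(visit_dist)),
         absorbing_frequency = sum(visit_dist[mdp$absorbing])),
    class = "imotiv_trajectory")
}

#' @export
print.imotiv_trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d steps, visit entropy %.4f nats, absorbing frequency %.4f>\n",
              length(x$actions), x$visit_entropy, x$absorbing_frequency))
  invisible(x)
}
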