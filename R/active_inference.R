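#' Variational free energy of a belief given an observation
#'
#' Computes F = E_q[-log P(s, o)] - H(q), the energy-minus-entropy form, and
#' independently the equivalent surprise-plus-divergence form
#' F = -log P(o) + KL(q || P(s|o)). The two routes agree to machine
#' precision for any belief, and F upper-bounds the surprise -log P(o), with
#' equality exactly when q is the Bayesian posterior.
#'
#' An observation with zero marginal likelihood has infinite surprise; this
#' is reported explicitly as `Inf`, never as `NaN`.
#'
#' @param gm a [generative_model()].
#' @param q belief over hidden states: a [categorical()] or bare vector.
#' @param o observation index (1-based).
#' @param prior optional prior over states; defaults to `gm$state_prior`.
#' @return A tibble with one row and columns `total`, `energy`, `entropy`,
#'   `surprise`, `divergence` (all in nats). `total = energy - entropy` and
#'   `total = surprise + divergence` up to floating point.
#' @export
variational_free_energy <- function(gm, q, o, prior = NULL) {
  q <- as.numeric(as_categorical(q))
  prior <- prior %||% gm$state_prior
  if (length(q) != gm$n_states) abort("belief length must equal n_states")
  if (o < 1 || o > gm$n_obs) abort("observation index out of range")
  joint_o <- gm$likelihood[o, ] * prior       # P(s, o) as a function of s
  p_o <- sum(joint_o)                          # marginal P(o)
  # energy route: E_q[-log P(s,o)] - H(q) = sum_q q log(q / P(s,o))
  energy <- if (any(q > 0 & joint_o == 0)) Inf else -sum(
    q[q > 0] * log(joint_o[q > 0]))
  ent <- entropy(categorical(q))
  total <- energy - ent
  # surprise + divergence route, computed independently
  surprise <- if (p_o > 0) -log(p_o) else Inf
  if (p_o > 0) {
    post <- joint_o / p_o
    divergence <- if (any(q > 0 & post == 0)) Inf else sum(xlogxy(q, post))
  } else {
    divergence <- Inf
  }
  tibble::tibble(total = total, energy = energy, entropy = ent,
                 surprise = surprise, divergence = divergence)
}

#' Exact perceptual posterior (free-energy minimiser)
#'
#' The belief that minimises variational free energy over unconstrained
#' categoricals is the exact Bayesian posterior
#' P(s|o) = P(o|s) P(s) / P(o); at this belief F equals the surprise
#' -log P(o).
#'
#' @inheritParams variational_free_energy
#' @param prior prior belief over states (defaults to the model's state
#'   prior).
#' @return A [categorical()] posterior over hidden states.
#' @export
perceptual_posterior <- function(gm, o, prior = NULL) {
  prior <- as.numeric(as_categorical(prior %||% gm$state_prior))
  if (o < 1 || o > gm$n_obs) abort("observation index out of range")
  unnorm <- gm$likelihood[o, ] * prior
  z <- sum(unnorm)
  if (z <= 0) {
    abort(sprintf("observation %d has zero marginal probability under the prior; posterior undefined", o))
  }
  categorical(unnorm / z)
}

#' Roll a generative model forward under an open-loop policy
#'
#' Propagates the initial belief through the policy's transition kernels to
#' obtain the policy-conditioned state prior Q(s_t | pi) at every timestep,
#' and pushes each through the likelihood for the predicted observation
#' distribution Q(o_t | pi). Timestep 0 is the initial belief itself;
#' control `policy[t]` drives the transition into timestep t.
#'
#' @param gm a [generative_model()].
#' @param q0 initial belief over states.
#' @param policy integer vector of control indices (1-based), e.g. one row
#'   of [enumerate_policies()].
#' @return An object of class `imotiv_rollout`: list with `q_states` and
#'   `q_obs`, each a list of length `length(policy) + 1` (index t + 1 holds
#'   timestep t), and `policy`.
#' @export
rollout_policy <- function(gm, q0, policy) {
  q <- as.numeric(as_categorical(q0))
  if (length(q) != gm$n_states) abort("belief length must equal n_states")
  policy <- as.integer(policy)
  if (any(policy < 1 | policy > gm$n_controls)) {
    abort("policy contains control indices out of range")
  }
  q_states <- vector("list", length(policy) + 1L)
  q_obs <- vector("list", length(policy) + 1L)
  q_states[[1]] <- q
  q_obs[[1]] <- as.numeric(gm$likelihood %*% q)
  for (t in seq_along(policy)) {
    q <- as.numeric(gm$transitions[, , policy[t]] %*% q)
    q_states[[t + 1L]] <- q
    q_obs[[t + 1L]] <- as.numeric(gm$likelihood %*% q)
  }
  structure(list(q_states = q_states, q_obs = q_obs, policy = policy),
            class = "imotiv_rollout")
}

#' Expected free energy breakdown of a policy
#'
#' For each controlled timestep t = 1..depth computes every term of the
#' expected free energy G and its standard decompositions, from the exact
#' joint Q(s_t, o_t | pi) = Q(s_t | pi) P(o_t | s_t):
#' \itemize{
#'   \item `risk` = KL(Q(o_t|pi) || P(o)), divergence of predicted
#'     observations from the preference distribution;
#'   \item `ambiguity` = E over Q(s_t|pi) of H(P(o_t|s_t)), expected
#'     likelihood entropy;
#'   \item `expected_log_preference` = E over Q(o_t|pi) of log P(o)
#'     (expected utility);
#'   \item `information_gain` = I(s_t; o_t) under the joint, equal to the
#'     expected KL from the exact conditional Q(s_t|o_t,pi) to Q(s_t|pi);
#'   \item `energy` = E over the joint of -log(P(o_t) Q(s_t|o_t,pi)), the
#'     Helmholtz energy under the planning model that treats the preference
#'     as the observation marginal;
#'   \item `state_entropy` = H(Q(s_t|pi)).
#' }
#' Because the conditional is the exact Bayes inversion of the rollout
#' predictive, the three printed forms coincide as identities:
#' `risk + ambiguity = -expected_log_preference - information_gain
#' = energy - state_entropy`.
#'
#' A reachable observation with zero preference probability makes `risk`
#' (and `energy`) infinite at that timestep; this is reported explicitly.
#'
#' @inheritParams rollout_policy
#' @return An object of class `imotiv_efe`: a tibble with one row per
#'   controlled timestep and columns `t`, `risk`, `ambiguity`,
#'   `expected_log_preference`, `information_gain`, `energy`,
#'   `state_entropy`, `G` (= risk + ambiguity), plus attribute `policy`.
#' @export
efe_breakdown <- function(gm, q0, policy) {
  ro <- rollout_policy(gm, q0, policy)
  pref <- gm$preference
  rows <- purrr::map(seq_along(policy), function(t) {
    q_s <- ro$q_states[[t + 1L]]
    q_o <- ro$q_obs[[t + 1L]]
    # joint over (s, o): rows states, cols observations
    Jm <- q_s * t(gm$likelihood)
    risk <- if (any(q_o > 0 & pref == 0)) Inf else sum(xlogxy(q_o, pref))
    ambiguity <- sum(q_s * apply(gm$likelihood, 2, function(col) -sum(xlogx(col))))
    elp <- if (any(q_o > 0 & pref == 0)) -Inf else sum(q_o[q_o > 0] * log(pref[q_o > 0]))
    J <- joint_distribution(Jm)
    ig <- mutual_information(J, form = "expected_kl")
    # Helmholtz energy under the planning model P(o) Q(s | o, pi)
    h_s_given_o <- conditional_entropy(J, given = 2) # H(S|O)
    energy <- -elp + h_s_given_o
    s_ent <- entropy(categorical(q_s))
    tibble::tibble(t = t, risk = risk, ambiguity = ambiguity,
                   expected_log_preference = elp, information_gain = ig,
                   energy = energy, state_entropy = s_ent,
                   G = risk + ambiguity)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "policy") <- as.integer(policy)
  class(out) <- c("imotiv_efe", class(out))
  out
}

#' Expected free energy totals for every enumerated policy
#'
#' Convenience wrapper: enumerates all depth-`depth` policies, computes each
#' breakdown, and returns per-policy totals together with the softmax policy
#' posterior.
#'
#' @inheritParams rollout_policy
#' @param depth number of controlled steps to plan over.
#' @param cap enumeration cap, passed to [enumerate_policies()].
#' @return A tibble with one row per policy: `policy` (list-column of
#'   integer vectors), totals of each breakdown term, `G`, and `posterior`
#'   (softmax of -G).
#' @export
efe_policy_table <- function(gm, q0, depth, cap = 1e5) {
  pols <- enumerate_policies(gm$n_controls, depth, cap = cap)
  rows <- purrr::map(seq_len(nrow(pols)), function(i) {
    bd <- efe_breakdown(gm, q0, pols[i, ])
    tibble::tibble(
      policy_id = i,
      policy = list(as.integer(pols[i, ])),
      risk = sum(bd$risk), ambiguity = sum(bd$ambiguity),
      expected_log_preference = sum(bd$expected_log_preference),
      information_gain = sum(bd$information_gain),
      energy = sum(bd$energy), state_entropy = sum(bd$state_entropy),
      G = sum(bd$G))
  })
  out <- dplyr::bind_rows(rows)
  out$posterior <- as.numeric(policy_posterior(out$G))
  out
}

#' Softmax policy posterior from expected free energies
#'
#' Q(pi) proportional to exp(-G), the Bayesian-model-average prior over
#' policies. No temperature parameter: it is fixed at 1 (scale G yourself for
#' other temperatures). Policies with infinite G receive probability zero;
#' if every entry is infinite there is no viable policy and an error is
#' raised.
#'
#' @param G numeric vector of expected free energies in nats (`Inf`
#'   allowed).
#' @return A [categorical()] over policies.
#' @export
#' @examples
#' policy_posterior(c(0, log(2))) # c(2/3, 1/3)
policy_posterior <- function(G) {
  if (any(is.nan(G))) abort("G contains NaN")
  if (all(is.infinite(G) & G > 0)) abort("all policies have infinite expected free energy; no viable policy")
  logw <- -G
  p <- exp(logw - logsumexp(logw))
  categorical(p)
}

#' Marginal distribution over first controls
#'
#' Collapses a policy posterior onto the first control of each policy:
#' Q(u) = sum over policies starting with u of Q(pi). This is the
#' distribution actions are sampled from at each planning step.
#'
#' @param q_pi [categorical()] (or vector) over policies.
#' @param policies integer matrix of policies, rows aligned with `q_pi`
#'   (as returned by [enumerate_policies()]).
#' @param n_controls total number of controls.
#' @return A [categorical()] over controls `1..n_controls`.
#' @export
action_marginal <- function(q_pi, policies, n_controls) {
  q_pi <- as.numeric(as_categorical(q_pi))
  if (nrow(policies) != length(q_pi)) {
    abort("'q_pi' must have one entry per policy row")
  }
  first <- policies[, 1]
  p <- vapply(seq_len(n_controls), function(u) sum(q_pi[first == u]),
              numeric(1))
  categorical(p)
}

#' Sample a control from the action marginal
#'
#' @inheritParams action_marginal
#' @param seed integer seed (required: sampling is the only stochastic step
#'   in action selection and must be replayable).
#' @return A single control index.
#' @export
sample_action <- function(q_pi, policies, n_controls, seed) {
  m <- as.numeric(action_marginal(q_pi, policies, n_controls))
  withr::local_seed(seed)
  sample.int(n_controls, 1, prob = m)
}

#' Generalized free energy of a policy distribution
#'
#' F = E_{q_pi}[G] - H(q_pi): the expected EFE under a candidate policy
#' distribution minus that distribution's entropy. Over all distributions it
#' is minimised exactly by the softmax posterior [policy_posterior()], where
#' it equals the negative log partition -log sum exp(-G).
#'
#' @param q_pi candidate policy distribution.
#' @param G numeric vector of per-policy expected free energies (nats).
#' @return Scalar generalized free energy in nats.
#' @export
generalized_free_energy <- function(q_pi, G) {
  q <- as.numeric(as_categorical(q_pi))
  if (length(q) != length(G)) abort("'q_pi' and 'G' must have equal length")
  expected <- sum(q[q > 0] * G[q > 0])
  expected - entropy(categorical(q))
}
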