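#' Action-sequence to final-observation channel
#'
#' Builds the channel whose capacity is n-step empowerment: one row per
#' action sequence of length `depth` (lexicographic order, matching
#' [enumerate_policies()]), columns over the final observation (or the final
#' state when `use_observations = FALSE`). Row j is the start belief pushed
#' through the sequence's transition kernels and, for observation
#' empowerment, through the likelihood. A point-mass start belief recovers
#' state-indexed empowerment; a general belief gives empowerment of a
#' belief state.
#'
#' @param gm a [generative_model()].
#' @param start either a single state index or a belief vector /
#'   [categorical()] over states.
#' @param depth number of action steps (>= 1).
#' @param use_observations if `TRUE` (default) the channel output is the
#'   final observation O_T; if `FALSE`, the final state S_T.
#' @param cap enumeration cap on `n_controls ^ depth`.
#' @return A [channel()] with `n_controls ^ depth` rows.
#' @export
action_observation_channel <- function(gm, start, depth,
                                       use_observations = TRUE, cap = 1e5) {
  if (depth < 1) abort("'depth' must be >= 1")
  q0 <- start_belief(gm, start)
  seqs <- enumerate_policies(gm$n_controls, depth, cap = cap)
  out_dim <- if (use_observations) gm$n_obs else gm$n_states
  M <- matrix(0, nrow = nrow(seqs), ncol = out_dim)
  for (j in seq_len(nrow(seqs))) {
    q <- q0
    for (t in seq_len(depth)) {
      q <- as.numeric(gm$transitions[, , seqs[j, t]] %*% q)
    }
    M[j, ] <- if (use_observations) as.numeric(gm$likelihood %*% q) else q
  }
  channel(M)
}

start_belief <- function(gm, start) {
  if (length(start) == 1 && is.numeric(start) && start == round(start)) {
    if (start < 1 || start > gm$n_states) abort("start state index out of range")
    q0 <- rep(0, gm$n_states)
    q0[start] <- 1
    q0
  } else {
    q0 <- as.numeric(as_categorical(start))
    if (length(q0) != gm$n_states) abort("start belief length must equal n_states")
    q0
  }
}

#' n-step empowerment of a state or belief
#'
#' Empowerment is the channel capacity of the action-sequence to
#' final-observation channel: the maximum mutual information between the
#' agent's next `depth` actions and the observation they lead to. It scores
#' both controllability (actions reliably select outcomes) and variety
#' (many outcomes are reachable). Computed by Blahut-Arimoto on the channel
#' from [action_observation_channel()].
#'
#' @inheritParams action_observation_channel
#' @param tol capacity tolerance in nats, passed to [channel_capacity()].
#' @param max_iter iteration cap, passed to [channel_capacity()].
#' @return An `imotiv_capacity` object (see [channel_capacity()]); its
#'   `capacity` element is the empowerment in nats.
#' @export
#' @examples
#' env <- make_gridworld(3, 3)
#' empowerment_at(env$model, start = 5, depth = 1)$capacity # log(5)
empowerment_at <- function(gm, start, depth, use_observations = TRUE,
                           tol = 1e-9, max_iter = 10000L, cap = 1e5) {
  ch <- action_observation_channel(gm, start, depth,
                                   use_observations = use_observations,
                                   cap = cap)
  channel_capacity(ch, tol = tol, max_iter = max_iter)
}

#' Per-state empowerment map
#'
#' Depth-n empowerment evaluated from a point-mass belief on every state.
#' Absorbing states score zero: every action sequence leads to the same
#' outcome distribution, so the channel carries no information.
#'
#' @param gm a [generative_model()] sharing the MDP's dynamics.
#' @param mdp optionally, the [mdp_spec()] whose labels (e.g. grid
#'   coordinates) are joined onto the result.
#' @inheritParams empowerment_at
#' @return A tibble with one row per state: `state`, `empowerment` (nats),
#'   `converged`, plus any label columns from `mdp$labels`.
#' @export
empowerment_map <- function(gm, depth, mdp = NULL, use_observations = TRUE,
                            tol = 1e-9, max_iter = 10000L, cap = 1e5) {
  rows <- purrr::map(seq_len(gm$n_states), function(s) {
    res <- empowerment_at(gm, s, depth, use_observations = use_observations,
                          tol = tol, max_iter = max_iter, cap = cap)
    tibble::tibble(state = s, empowerment = res$capacity,
                   converged = res$converged)
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(mdp) && !is.null(mdp$labels)) {
    out <- dplyr::left_join(out, mdp$labels, by = "state")
  }
  class(out) <- c("imotiv_empowerment_map", class(out))
  out
}

#' Numerical audit of the free-energy reading of empowerment
#'
#' Treats the policy (action sequence) as a latent variable, builds the
#' exact joint distribution over (policy, final state, final observation)
#' under a supplied policy distribution (default uniform over all
#' enumerated sequences), and computes every entropy, energy and
#' information term that appears when empowerment's mutual information
#' I(pi; o_T) is rearranged into free-energy-like forms. Alongside the
#' terms it reports the residuals of several candidate identities. The
#' standard chain rule H(o_T|pi) = ambiguity_T + I(s_T; o_T | pi) is an
#' exact identity here (o_T depends on pi only through s_T); variants that
#' swap H(o_T) for H(pi) are generally not identities and their residuals
#' quantify by how much they fail on the given model.
#'
#' @param gm a [generative_model()].
#' @param q0 start belief over states (vector or [categorical()]).
#' @param depth number of action steps.
#' @param policy_dist optional distribution over the enumerated action
#'   sequences; default uniform. (The capacity-achieving distribution is a
#'   different object, obtainable from [empowerment_at()].)
#' @param cap enumeration cap.
#' @return An object of class `imotiv_empowerment_audit`: a list with
#'   \describe{
#'     \item{terms}{tibble of named terms (nats): `mutual_information`
#'       I(pi;o_T), `policy_entropy` H(pi), `obs_entropy` H(o_T),
#'       `conditional_obs_entropy` H(o_T|pi), `final_obs_energy`
#'       E[-log P(o_T|s_T)], `conditional_state_entropy` H(s_T|pi),
#'       `ambiguity_T`, `state_information_gain` I(pi;s_T),
#'       `obs_state_mi_given_policy` I(s_T;o_T|pi)}
#'     \item{residuals}{tibble of named residuals: each candidate identity's
#'       left side minus right side}
#'   }
#' @export
empowerment_free_energy_audit <- function(gm, q0, depth, policy_dist = NULL,
                                          cap = 1e5) {
  q0 <- start_belief(gm, q0)
  seqs <- enumerate_policies(gm$n_controls, depth, cap = cap)
  n_pol <- nrow(seqs)
  p_pi <- as.numeric(as_categorical(policy_dist %||% rep(1 / n_pol, n_pol)))
  if (length(p_pi) != n_pol) abort("'policy_dist' must have one entry per action sequence")

  # exact joint P(pi, s_T, o_T) = P(pi) Q(s_T|pi) P(o_T|s_T)
  J <- array(0, dim = c(n_pol, gm$n_states, gm$n_obs))
  for (j in seq_len(n_pol)) {
    q <- q0
    for (t in seq_len(depth)) {
      q <- as.numeric(gm$transitions[, , seqs[j, t]] %*% q)
    }
    J[j, , ] <- p_pi[j] * (q * t(gm$likelihood))
  }

  j_pi_o <- apply(J, c(1, 3), sum)   # P(pi, o_T)
  j_pi_s <- apply(J, c(1, 2), sum)   # P(pi, s_T)
  h_pi <- entropy(categorical(p_pi))
  Jpo <- joint_distribution(j_pi_o)
  Jps <- joint_distribution(j_pi_s)
  mi_pi_o <- mutual_information(Jpo, form = "kl_joint")
  mi_pi_s <- mutual_information(Jps, form = "kl_joint")
  h_o <- entropy(marginal(Jpo, 2))
  h_o_given_pi <- conditional_entropy(Jpo, given = 1)
  h_s_given_pi <- conditional_entropy(Jps, given = 1)
  # E[-log P(o_T|s_T)] over the full joint == expected likelihood entropy
  p_s <- apply(J, 2, sum)
  lik_ent <- apply(gm$likelihood, 2, function(col) -sum(xlogx(col)))
  ambiguity_T <- sum(p_s * lik_ent)
  final_obs_energy <- ambiguity_T # identical by o_T independent of pi given s_T
  # I(s_T; o_T | pi) = sum_pi P(pi) I(s_T; o_T | pi = j)
  mi_s_o_given_pi <- 0
  for (j in seq_len(n_pol)) {
    if (p_pi[j] > 0) {
      mi_s_o_given_pi <- mi_s_o_given_pi + p_pi[j] *
        mutual_information(joint_distribution(J[j, , ] / p_pi[j]),
                           form = "kl_joint")
    }
  }

  terms <- tibble::tibble(
    term = c("mutual_information", "policy_entropy", "obs_entropy",
             "conditional_obs_entropy", "final_obs_energy",
             "conditional_state_entropy", "ambiguity_T",
             "state_information_gain", "obs_state_mi_given_policy"),
    nats = c(mi_pi_o, h_pi, h_o, h_o_given_pi, final_obs_energy,
             h_s_given_pi, ambiguity_T, mi_pi_s, mi_s_o_given_pi))

  f_emp <- -mi_pi_o # "free energy of empowerment": minimised as I is maximised
  residuals <- tibble::tibble(
    identity = c(
      "standard_mi (H(oT) - H(oT|pi) - I(pi;oT))",
      "printed_policy_entropy_mi (H(pi) - H(oT|pi) - I(pi;oT))",
      "printed_double_negative (-H(pi) - H(oT|pi) - F)",
      "energy_entropy_form (H(oT|pi) - H(pi) - F)",
      "final_state_decomposition (E[-log P(oT|sT)] + H(sT|pi) - H(pi) - F)",
      "ambiguity_minus_state_ig (ambiguity_T - I(pi;sT) - F)",
      "chain_rule (H(oT|pi) - ambiguity_T - I(sT;oT|pi))"),
    residual = c(
      h_o - h_o_given_pi - mi_pi_o,
      h_pi - h_o_given_pi - mi_pi_o,
      -h_pi - h_o_given_pi - f_emp,
      h_o_given_pi - h_pi - f_emp,
      final_obs_energy + h_s_given_pi - h_pi - f_emp,
      ambiguity_T - mi_pi_s - f_emp,
      h_o_given_pi - ambiguity_T - mi_s_o_given_pi))

  structure(list(terms = terms, residuals = residuals, depth = depth,
                 policy_dist = p_pi),
            class = "imotiv_empowerment_audit")
}

#' @export
print.imotiv_empowerment_audit <- function(x, ...) {
  cat(sprintf("<empowerment free-energy audit, depth %d>\nTerms (nats):\n", x$depth))
  print(as.data.frame(x$terms), row.names = FALSE)
  cat("Identity residuals (left - right, nats):\n")
  print(as.data.frame(x$residuals), row.names = FALSE)
  invisible(x)
}
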