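#' Write a generative model or MDP to a YAML config
#'
#' Models, MDPs and channels round-trip through a plain-text YAML schema:
#' nested mappings of scalars and lists of floats, no binary payloads.
#' Matrices are stored as lists of rows; transition tensors as one
#' `n_states x n_states` matrix per control, in control order.
#'
#' @param x a [generative_model()], [mdp_spec()] or [channel()].
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_imotiv_yaml <- function(x, path) {
  obj <- if (inherits(x, "imotiv_genmodel")) {
    list(type = "generative_model",
         n_states = x$n_states, n_obs = x$n_obs, n_controls = x$n_controls,
         horizon = x$horizon,
         likelihood = mat_to_rows(x$likelihood),
         transitions = lapply(seq_len(x$n_controls), function(u) {
           mat_to_rows(x$transitions[, , u])
         }),
         state_prior = as.numeric(x$state_prior),
         preference = as.numeric(x$preference))
  } else if (inherits(x, "imotiv_mdp")) {
    list(type = "mdp",
         n_states = x$n_states, n_actions = x$n_actions,
         absorbing = as.integer(x$absorbing),
         transitions = lapply(seq_len(x$n_actions), function(a) {
           mat_to_rows(x$transitions[, , a])
         }),
         labels = if (is.null(x$labels)) NULL else as.list(x$labels))
  } else if (inherits(x, "imotiv_channel")) {
    list(type = "channel", matrix = mat_to_rows(unclass(x)))
  } else {
    abort("unsupported object type for YAML serialization")
  }
  yaml::write_yaml(obj, path, precision = 17)
  invisible(path)
}

#' Read a generative model, MDP or channel from a YAML config
#'
#' @param path file written by [write_imotiv_yaml()] (or hand-authored in
#'   the same schema).
#' @return The reconstructed object, revalidated on construction.
#' @export
read_imotiv_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  switch(obj$type,
    generative_model = {
      Tr <- array(0, dim = c(obj$n_states, obj$n_states, obj$n_controls))
      for (u in seq_len(obj$n_controls)) {
        Tr[, , u] <- rows_to_mat(obj$transitions[[u]])
      }
      generative_model(
        likelihood = rows_to_mat(obj$likelihood),
        transitions = Tr,
        state_prior = obj$state_prior,
        preference = obj$preference,
        horizon = obj$horizon)
    },
    mdp = {
      Tr <- array(0, dim = c(obj$n_states, obj$n_states, obj$n_actions))
      for (a in seq_len(obj$n_actions)) {
        Tr[, , a] <- rows_to_mat(obj$transitions[[a]])
      }
      labels <- if (is.null(obj$labels)) NULL else tibble::as_tibble(obj$labels)
      mdp_spec(Tr, absorbing = obj$absorbing %||% integer(0), labels = labels)
    },
    channel = channel(rows_to_mat(obj$matrix)),
    abort(sprintf("unknown config type '%s'", obj$type)))
}

mat_to_rows <- function(m) lapply(seq_len(nrow(m)), function(i) as.numeric(m[i, ]))

rows_to_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))

#' Export a gridworld as an edge list
#'
#' One row per (state, action, next_state) triple with positive probability,
#' for visual inspection or graph tooling.
#'
#' @param mdp an [mdp_spec()].
#' @return A tibble with columns `state`, `action`, `next_state`, `prob`.
#' @export
mdp_edge_list <- function(mdp) {
  rows <- list()
  for (a in seq_len(mdp$n_actions)) {
    idx <- which(mdp$transitions[, , a] > 0, arr.ind = TRUE)
    rows[[a]] <- tibble::tibble(
      state = idx[, 2], action = a, next_state = idx[, 1],
      prob = mdp$transitions[, , a][idx])
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$state, .data$action,
                 .data$next_state)
}
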