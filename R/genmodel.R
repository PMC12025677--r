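#' Discrete generative model (finite POMDP)
#'
#' Container for the four distributions that define a discrete
#' partially-observed generative model:
#' a likelihood P(o|s), per-control transition kernels P(s'|s,u), a prior
#' over the initial hidden state, and a state-independent preference
#' distribution over observations used as the goal prior in expected free
#' energy. Orientation conventions, fixed package-wide and enforced by
#' [validate_model()]:
#' \itemize{
#'   \item `likelihood`: observations in rows, states in columns; every
#'     column is a distribution over observations.
#'   \item `transitions`: a 3-d array indexed `[next_state, state, control]`;
#'     every column of every control slice is a distribution over next
#'     states.
#' }
#'
#' @param likelihood numeric matrix, `n_obs x n_states`, column-stochastic.
#' @param transitions numeric array, `n_states x n_states x n_controls`,
#'   with `transitions[, s, u]` the distribution of the next state.
#' @param state_prior [categorical()] (or bare vector) over initial states.
#' @param preference [categorical()] (or bare vector) over observations;
#'   defaults to uniform, the purely epistemic regime in which expected free
#'   energy reduces to negative information gain.
#' @param horizon default planning horizon (number of controlled steps).
#' @return An object of class `imotiv_genmodel`.
#' @export
generative_model <- function(likelihood, transitions, state_prior,
                             preference = NULL, horizon = 1L) {
  likelihood <- as.matrix(likelihood)
  n_states <- ncol(likelihood)
  n_obs <- nrow(likelihood)
  transitions <- as.array(transitions)
  if (length(dim(transitions)) == 2) {
    transitions <- array(transitions, dim = c(dim(transitions), 1L))
  }
  if (!all(dim(transitions)[1:2] == n_states)) {
    abort("'transitions' must be n_states x n_states x n_controls")
  }
  gm <- structure(
    list(likelihood = likelihood,
         transitions = transitions,
         state_prior = as.numeric(as_categorical(state_prior)),
         preference = as.numeric(as_categorical(
           preference %||% rep(1 / n_obs, n_obs))),
         horizon = as.integer(horizon),
         n_states = n_states,
         n_obs = n_obs,
         n_controls = dim(transitions)[3]),
    class = "imotiv_genmodel")
  rep_v <- validate_model(gm)
  errs <- rep_v[rep_v$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    abort(paste0("invalid generative model:\n  ",
                 paste(errs$message, collapse = "\n  ")))
  }
  gm
}

#' @export
print.imotiv_genmodel <- function(x, ...) {
  cat(sprintf("<generative model: %d states, %d observations, %d controls, horizon %d>\n",
              x$n_states, x$n_obs, x$n_controls, x$horizon))
  invisible(x)
}

#' Finite MDP specification
#'
#' A fully observed Markov decision process: per-action transition kernels
#' plus an optional set of absorbing states (states that self-loop under
#' every action, the standard operationalisation of terminal/dead states
#' that contribute zero path entropy forever).
#'
#' @param transitions numeric array `n_states x n_states x n_actions`, with
#'   `transitions[, s, a]` the distribution of the next state.
#' @param absorbing integer vector of absorbing state indices (may be empty).
#' @param labels optional data frame of per-state labels (e.g. grid
#'   coordinates).
#' @return An object of class `imotiv_mdp`.
#' @export
mdp_spec <- function(transitions, absorbing = integer(0), labels = NULL) {
  transitions <- as.array(transitions)
  n_states <- dim(transitions)[1]
  if (dim(transitions)[2] != n_states) {
    abort("'transitions' must be n_states x n_states x n_actions")
  }
  n_actions <- dim(transitions)[3]
  absorbing <- as.integer(absorbing)
  for (s in seq_len(n_states)) {
    for (a in seq_len(n_actions)) {
      stop_not_prob(transitions[, s, a], sprintf("transition column (s=%d, a=%d)", s, a))
      transitions[, s, a] <- transitions[, s, a] / sum(transitions[, s, a])
    }
  }
  for (s in absorbing) {
    for (a in seq_len(n_actions)) {
      if (abs(transitions[s, s, a] - 1) > .prob_tol) {
        abort(sprintf("state %d declared absorbing but P(s|s,a=%d) = %.6f != 1",
                      s, a, transitions[s, s, a]))
      }
    }
  }
  structure(
    list(transitions = transitions,
         n_states = n_states,
         n_actions = n_actions,
         absorbing = absorbing,
         labels = labels),
    class = "imotiv_mdp")
}

#' @export
print.imotiv_mdp <- function(x, ...) {
  cat(sprintf("<MDP: %d states, %d actions, %d absorbing>\n",
              x$n_states, x$n_actions, length(x$absorbing)))
  invisible(x)
}

#' Validate a generative model's stochasticity and support invariants
#'
#' A pure reporting operation: returns a tibble with one row per violated
#' invariant, naming the offending slice. An empty tibble means the model is
#' valid. A preference distribution with zero-probability observations is
#' reported as a warning (risk terms take the log of the preference, so
#' policies that reach such observations score infinite risk), not an error.
#'
#' @param gm an `imotiv_genmodel` (or a bare list with the same fields).
#' @return A tibble with columns `component`, `index`, `severity`, `message`.
#' @export
validate_model <- function(gm) {
  rows <- list()
  add <- function(component, index, severity, message) {
    rows[[length(rows) + 1L]] <<- tibble::tibble(
      component = component, index = index,
      severity = severity, message = message)
  }
  A <- gm$likelihood
  for (s in seq_len(ncol(A))) {
    col <- A[, s]
    if (any(col < 0)) {
      add("likelihood", sprintf("s=%d", s), "error",
          sprintf("likelihood column s=%d has negative entries", s))
    } else if (abs(sum(col) - 1) > 1e-8) {
      add("likelihood", sprintf("s=%d", s), "error",
          sprintf("likelihood column s=%d sums to %.10f, not 1", s, sum(col)))
    }
  }
  Tr <- gm$transitions
  n_controls <- dim(Tr)[3]
  for (u in seq_len(n_controls)) {
    for (s in seq_len(dim(Tr)[2])) {
      col <- Tr[, s, u]
      if (any(col < 0)) {
        add("transitions", sprintf("s=%d,u=%d", s, u), "error",
            sprintf("transition column (s=%d, u=%d) has negative entries", s, u))
      } else if (abs(sum(col) - 1) > 1e-8) {
        add("transitions", sprintf("s=%d,u=%d", s, u), "error",
            sprintf("transition column (s=%d, u=%d) sums to %.10f, not 1",
                    s, u, sum(col)))
      }
    }
  }
  for (nm in c("state_prior", "preference")) {
    p <- gm[[nm]]
    if (any(p < 0)) {
      add(nm, "", "error", sprintf("%s has negative entries", nm))
    } else if (abs(sum(p) - 1) > 1e-8) {
      add(nm, "", "error", sprintf("%s sums to %.10f, not 1", nm, sum(p)))
    }
  }
  zero_pref <- which(gm$preference == 0)
  if (length(zero_pref) > 0) {
    add("preference", paste(zero_pref, collapse = ","), "warning",
        sprintf("preference assigns zero probability to observation(s) %s; policies reaching them score infinite risk",
                paste(zero_pref, collapse = ", ")))
  }
  if (length(rows) == 0) {
    tibble::tibble(component = character(), index = character(),
                   severity = character(), message = character())
  } else {
    dplyr::bind_rows(rows)
  }
}

#' Gridworld environment generator
#'
#' Builds a width x height gridworld with the five-action set
#' up/down/left/right/stay. Moves that would leave the grid collapse onto
#' "stay". With probability `slip` the agent ignores its action and moves to
#' a uniformly random one of the four cardinal directions (wall-blocked
#' directions again collapsing onto the current cell). Absorbing cells
#' self-loop under every action. The observation model is the identity
#' corrupted by `observation_noise`: the true cell is observed with
#' probability `1 - observation_noise`, the remaining mass spread uniformly
#' over the other cells. The preference distribution defaults to uniform.
#'
#' States are numbered column-major in (x, y): cell (x, y) with x in 1..width,
#' y in 1..height has index `(y - 1) * width + x`.
#'
#' @param width,height grid dimensions; `width * height >= 2`.
#' @param absorbing_cells integer vector of absorbing state indices.
#' @param slip slip probability in `[0, 1)`.
#' @param observation_noise observation corruption probability in `[0, 1)`.
#' @param horizon default planning horizon stored on the generative model.
#' @return A list with elements `mdp` (an [mdp_spec()]) and `model`
#'   (a [generative_model()] with uniform state prior and preference).
#' @export
#' @examples
#' env <- make_gridworld(3, 3, absorbing_cells = 5)
#' env$mdp
make_gridworld <- function(width, height, absorbing_cells = integer(0),
                           slip = 0, observation_noise = 0, horizon = 1L) {
  if (width * height < 2) abort("grid must have at least 2 cells")
  n <- width * height
  absorbing_cells <- as.integer(absorbing_cells)
  if (any(absorbing_cells < 1 | absorbing_cells > n)) {
    abort(sprintf("absorbing cell out of range 1..%d", n))
  }
  if (slip < 0 || slip >= 1) abort("'slip' must be in [0, 1)")
  if (observation_noise < 0 || observation_noise >= 1) {
    abort("'observation_noise' must be in [0, 1)")
  }
  cell <- function(x, y) (y - 1L) * width + x
  coords <- tibble::tibble(
    state = seq_len(n),
    x = rep(seq_len(width), times = height),
    y = rep(seq_len(height), each = width))
  # destination of a cardinal move (or stay) with wall-blocking
  move_dest <- function(x, y, a) {
    nx <- x + switch(a, up = 0, down = 0, left = -1, right = 1, stay = 0)
    ny <- y + switch(a, up = 1, down = -1, left = 0, right = 0, stay = 0)
    if (nx < 1 || nx > width || ny < 1 || ny > height) cell(x, y) else cell(nx, ny)
  }
  actions <- c("up", "down", "left", "right", "stay")
  cardinal <- c("up", "down", "left", "right")
  Tr <- array(0, dim = c(n, n, 5L))
  for (s in seq_len(n)) {
    x <- coords$x[s]; y <- coords$y[s]
    if (s %in% absorbing_cells) {
      Tr[s, s, ] <- 1
      next
    }
    slip_dest <- vapply(cardinal, function(a) move_dest(x, y, a), numeric(1))
    for (ai in seq_along(actions)) {
      d <- move_dest(x, y, actions[ai])
      Tr[d, s, ai] <- Tr[d, s, ai] + (1 - slip)
      for (sd in slip_dest) Tr[sd, s, ai] <- Tr[sd, s, ai] + slip / 4
    }
  }
  mdp <- mdp_spec(Tr, absorbing = absorbing_cells, labels = coords)
  A <- matrix(observation_noise / (n - 1), nrow = n, ncol = n)
  diag(A) <- 1 - observation_noise
  gm <- generative_model(
    likelihood = A,
    transitions = Tr,
    state_prior = rep(1 / n, n),
    preference = rep(1 / n, n),
    horizon = horizon)
  list(mdp = mdp, model = gm)
}

#' Random generative model drawn from symmetric Dirichlet priors
#'
#' Every conditional distribution (likelihood columns, transition columns,
#' state prior, preference) is an independent symmetric Dirichlet draw with
#' the given concentration. Large concentrations give near-uniform
#' conditionals; concentrations below 1 give sparse, spiky ones.
#' Reproducible under `seed` (the RNG state is restored on exit).
#'
#' @param n_states,n_obs,n_controls cardinalities, each >= 2.
#' @param concentration positive Dirichlet concentration (default 1: uniform
#'   on the simplex).
#' @param seed integer seed.
#' @param horizon default planning horizon.
#' @return A [generative_model()].
#' @export
make_random_model <- function(n_states, n_obs, n_controls,
                              concentration = 1, seed,
                              horizon = 1L) {
  if (n_states < 2 || n_obs < 2 || n_controls < 2) {
    abort("all cardinalities must be >= 2")
  }
  if (concentration <= 0) abort("'concentration' must be positive")
  withr::local_seed(seed)
  rdirichlet <- function(k) {
    g <- stats::rgamma(k, shape = concentration)
    g / sum(g)
  }
  A <- vapply(seq_len(n_states), function(s) rdirichlet(n_obs),
              numeric(n_obs))
  Tr <- array(0, dim = c(n_states, n_states, n_controls))
  for (u in seq_len(n_controls)) {
    Tr[, , u] <- vapply(seq_len(n_states), function(s) rdirichlet(n_states),
                        numeric(n_states))
  }
  generative_model(
    likelihood = A,
    transitions = Tr,
    state_prior = rdirichlet(n_states),
    preference = rdirichlet(n_obs),
    horizon = horizon)
}

#' Enumerate all fixed-depth policies (control sequences)
#'
#' A policy here is a finite open-loop sequence of control indices. All
#' `n_controls ^ depth` sequences are returned in lexicographic order, the
#' row ordering every policy-indexed quantity in the package uses.
#'
#' @param n_controls number of available controls.
#' @param depth sequence length.
#' @param cap safety cap on the number of policies (default 1e5): exhaustive
#'   enumeration is exponential in depth, so exceeding the cap is an error
#'   telling the user to reduce the depth rather than a silent stall.
#' @return An integer matrix with one row per policy, `depth` columns,
#'   controls numbered from 1.
#' @export
#' @examples
#' enumerate_policies(2, 3)
enumerate_policies <- function(n_controls, depth, cap = 1e5) {
  n_pol <- n_controls^depth
  if (n_pol > cap) {
    abort(sprintf(
      "%d^%d = %g policies exceeds the enumeration cap (%g); reduce depth",
      n_controls, depth, n_pol, cap))
  }
  # lexicographic: first column varies slowest
  g <- do.call(expand.grid, rep(list(seq_len(n_controls)), depth))
  g <- as.matrix(g[do.call(order, as.data.frame(g)), , drop = FALSE])
  dimnames(g) <- NULL
  g
}
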