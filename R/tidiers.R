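#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a channel-capacity result
#'
#' @param x an `imotiv_capacity` object.
#' @param ... unused.
#' @return A tibble with one row per channel input: `input`, `probability`
#'   (the capacity-achieving input distribution).
#' @method tidy imotiv_capacity
#' @export
tidy.imotiv_capacity <- function(x, ...) {
  tibble::tibble(input = seq_along(x$input_distribution),
                 probability = as.numeric(x$input_distribution))
}

#' @rdname tidy.imotiv_capacity
#' @return For `glance()`: a one-row tibble with `capacity` (nats),
#'   `capacity_bits`, `iterations`, `converged`, `bound_gap`.
#' @method glance imotiv_capacity
#' @export
glance.imotiv_capacity <- function(x, ...) {
  tibble::tibble(capacity = x$capacity,
                 capacity_bits = nats_to_bits(x$capacity),
                 iterations = x$iterations,
                 converged = x$converged,
                 bound_gap = x$bound_gap)
}

#' Tidy a maximum-occupancy fit
#'
#' @param x an `imotiv_mop_fit` from [mop_optimize()].
#' @param ... unused.
#' @return A tibble with one row per (state, action): `state`, `action`,
#'   `probability`, and the state's `value` (nats).
#' @method tidy imotiv_mop_fit
#' @export
tidy.imotiv_mop_fit <- function(x, ...) {
  pol <- unclass(x$policy)
  tibble::tibble(
    state = rep(seq_len(nrow(pol)), each = ncol(pol)),
    action = rep(seq_len(ncol(pol)), times = nrow(pol)),
    probability = as.numeric(t(pol)),
    value = rep(x$value, each = ncol(pol)))
}

#' @rdname tidy.imotiv_mop_fit
#' @return For `glance()`: one row with `alpha`, `beta`, `gamma`,
#'   `iterations`, `sup_change`, `mean_value`.
#' @method glance imotiv_mop_fit
#' @export
glance.imotiv_mop_fit <- function(x, ...) {
  tibble::tibble(alpha = x$params$alpha, beta = x$params$beta,
                 gamma = x$params$gamma, iterations = x$iterations,
                 sup_change = x$sup_change, mean_value = mean(x$value))
}

#' Tidy a trajectory
#'
#' @param x an `imotiv_trajectory` from [simulate_trajectory()].
#' @param ... unused.
#' @return A tibble with one row per step: `t` (from 0), `state`, `action`,
#'   `next_state`.
#' @method tidy imotiv_trajectory
#' @export
tidy.imotiv_trajectory <- function(x, ...) {
  n <- length(x$actions)
  tibble::tibble(t = seq_len(n) - 1L,
                 state = x$states[seq_len(n)],
                 action = x$actions,
                 next_state = x$states[seq_len(n) + 1L])
}

#' @rdname tidy.imotiv_trajectory
#' @return For `glance()`: one row with `steps`, `reward`, `visit_entropy`,
#'   `absorbing_frequency`.
#' @method glance imotiv_trajectory
#' @export
glance.imotiv_trajectory <- function(x, ...) {
  tibble::tibble(steps = length(x$actions), reward = x$reward,
                 visit_entropy = x$visit_entropy,
                 absorbing_frequency = x$absorbing_frequency)
}
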