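#' @importFrom ggplot2 autoplot ggplot aes geom_tile geom_col geom_line
#'   facet_wrap labs scale_fill_viridis_c position_dodge
#' @export
ggplot2::autoplot

#' Plot an empowerment map as a grid heat map
#'
#' Requires the map to carry `x`/`y` grid coordinates (joined from the
#' MDP labels via `empowerment_map(..., mdp = )`); falls back to a per-state
#' column chart otherwise.
#'
#' @param object an `imotiv_empowerment_map` tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot imotiv_empowerment_map
#' @export
autoplot.imotiv_empowerment_map <- function(object, ...) {
  if (all(c("x", "y") %in% names(object))) {
    ggplot(object, aes(x = .data$x, y = .data$y, fill = .data$empowerment)) +
      geom_tile() +
      scale_fill_viridis_c() +
      labs(fill = "empowerment\n(nats)", x = NULL, y = NULL)
  } else {
    ggplot(object, aes(x = factor(.data$state), y = .data$empowerment)) +
      geom_col() +
      labs(x = "state", y = "empowerment (nats)")
  }
}

#' Plot an expected-free-energy breakdown
#'
#' Per-timestep stacked view of the risk and ambiguity components of G.
#'
#' @param object an `imotiv_efe` tibble from [efe_breakdown()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot imotiv_efe
#' @export
autoplot.imotiv_efe <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "risk", "ambiguity")],
    cols = c("risk", "ambiguity"),
    names_to = "term", values_to = "nats")
  ggplot(long, aes(x = factor(.data$t), y = .data$nats, fill = .data$term)) +
    geom_col() +
    labs(x = "timestep", y = "expected free energy (nats)", fill = NULL)
}

#' Plot an agent-comparison report
#'
#' One panel per behavioural statistic, one bar per agent per seed.
#'
#' @param object an `imotiv_comparison` tibble from [run_comparison()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot imotiv_comparison
#' @export
autoplot.imotiv_comparison <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("visit_entropy", "absorbing_frequency", "mean_action_entropy"),
    names_to = "statistic", values_to = "value")
  ggplot(long, aes(x = .data$agent, y = .data$value,
                   group = factor(.data$seed))) +
    geom_col(position = position_dodge()) +
    facet_wrap(~statistic, scales = "free_y") +
    labs(x = NULL, y = NULL)
}

#' @importFrom rlang .data
NULL
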