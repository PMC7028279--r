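# broom-style tidiers for runs and sweeps.

#' Tidy a scenario run
#'
#' @param x An `sc_run`.
#' @param table Which trace to return: `"trace"` (per time-step and agent),
#'   `"flows"` (per time-step and supply edge) or `"trust"` (per time-step
#'   and buyer-supplier pair).
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.sc_run <- function(x, table = c("trace", "flows", "trust"), ...) {
  table <- match.arg(table)
  x[[table]]
}

#' One-row summary of a scenario run
#'
#' @param x An `sc_run`.
#' @param ... Unused.
#' @return A one-row tibble: scenario, delta, disruption type, onset, number
#'   of steps, per-healthcenter and overall window costs.
#' @export
glance.sc_run <- function(x, ...) {
  costs <- agent_cost(x)
  hc <- x$trace |> dplyr::distinct(.data$agent, .data$echelon)
  hc <- hc$agent[hc$echelon == "healthcenter"]
  tibble::tibble(
    scenario = x$config$scenario,
    delta = x$config$delta,
    tom = x$config$tom,
    disruption = x$disruption$type,
    stabilized_at = x$stabilized_at,
    onset = x$onset,
    steps = max(x$trace$t),
    trust_hc_cost = sum(costs$cost[costs$agent == "Trust HC"]),
    equal_hc_cost = sum(costs$cost[costs$agent == "Equal HC"]),
    overall_cost = sum(costs$cost)
  )
}

#' Tidy a delta sweep
#'
#' @param x An `sc_sweep` from [sweep_delta()].
#' @param ... Unused.
#' @return The sweep tibble (`delta`, `agent`, `echelon`, `cost`).
#' @export
tidy.sc_sweep <- function(x, ...) {
  tibble::as_tibble(x)
}
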