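# Miniature worlds with analytic steady states, used throughout the test
# suite and handy for exploring the dynamics interactively.

#' Build a miniature fixture world
#'
#' Three deterministic fixtures with documented steady states:
#' * `"dyad"`: one root distributor (produces its own stock) supplying one
#'   healthcenter; demand 10/step, lead time 1. Steady state: the
#'   healthcenter orders 10/step, the distributor ships 10/step.
#' * `"triad"`: manufacturer, distributor, healthcenter in a line; demand
#'   10/step, lead time 1. Steady state: production = orders = shipments =
#'   10/step at every echelon.
#' * `"full_tiny"`: the six-agent study network at demand 10/step, lead time
#'   2 — the default network scaled down by a factor of ten.
#'
#' @param kind One of `"dyad"`, `"triad"`, `"full_tiny"`.
#' @param demand Patient demand per healthcenter per step (default 10).
#' @return A list with elements `world` (an `sc_world`) and `steady_flow`
#'   (named numeric vector of per-agent steady throughput).
#' @examples
#' fx <- make_fixture("dyad")
#' fx$steady_flow
#' @export
make_fixture <- function(kind = c("dyad", "triad", "full_tiny"), demand = 10) {
  kind <- match.arg(kind)
  world <- switch(kind,
    dyad = supply_world(
      agents = data.frame(
        name = c("DS", "HC"), echelon = c("distributor", "healthcenter"),
        capacity = c(NA, NA), demand = c(NA, demand)
      ),
      edges = data.frame(seller = "DS", buyer = "HC"),
      params = world_params(lead_time = 1L, trust_window = 2L)
    ),
    triad = supply_world(
      agents = data.frame(
        name = c("MN", "DS", "HC"),
        echelon = c("manufacturer", "distributor", "healthcenter"),
        capacity = c(2 * demand, NA, NA), demand = c(NA, NA, demand)
      ),
      edges = data.frame(seller = c("MN", "DS"), buyer = c("DS", "HC")),
      params = world_params(lead_time = 1L, trust_window = 2L)
    ),
    full_tiny = build_network(
      scenario_config("custom", demand = list(type = "constant", value = demand))
    )
  )
  list(world = world, steady_flow = setNames(world$steady_flow, world$names))
}
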