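# Finite-horizon Theory-of-Mind planning. A planning agent rolls the world
# forward H steps with a disruption-blind copy of the transition (nominal
# capacities, mean demand), models every other agent as greedy with respect
# to its own reward, and picks the action maximizing its discounted return.
#
# Modeled agents are nested at depth 1: inside a rollout, a modeled planner
# models everyone else as scripted. Mutual best response is resolved by one
# sequential pass in the world's canonical agent order; with a single
# planning agent (every scenario shipped here) the pass is exact.

#' Planner configuration
#'
#' @param horizon Planning horizon `H` in time-steps (default 6, chosen so a
#'   three-echelon chain with lead time 2 can see the effects of a decision
#'   propagate end to end).
#' @param discount Discount factor `gamma` in (0, 1\] (default 0.9).
#' @param tom_agents Character vector of agents that plan with the
#'   Theory-of-Mind model; all others follow their scripted rule.
#' @param tie_tol Relative indifference threshold: an agent deviates from the
#'   earlier action in canonical order only when the alternative improves its
#'   planned return by more than this fraction (default `0.02`, i.e. 2 per cent). Strict
#'   floating-point ties essentially never occur, so the threshold is what
#'   makes the documented tie-break (proportional before preferential)
#'   operative: numerically negligible differences do not move a boundedly
#'   rational agent off its default rule.
#' @return A list of class `planner_config`.
#' @export
planner_config <- function(horizon = 6L, discount = 0.9, tom_agents = character(),
                           tie_tol = 0.02) {
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("configuration error: `horizon` must be >= 1", call. = FALSE)
  if (discount <= 0 || discount > 1) {
    stop("configuration error: `discount` must lie in (0, 1]", call. = FALSE)
  }
  if (tie_tol < 0) stop("configuration error: `tie_tol` must be >= 0", call. = FALSE)
  structure(list(horizon = horizon, discount = discount,
                 tom_agents = tom_agents, tie_tol = tie_tol),
            class = "planner_config")
}

# TRUE when `v` beats the incumbent `best` by more than the relative
# indifference threshold.
beats <- function(v, best, tol) {
  if (!is.finite(best)) return(v > best)
  v > best + tol * abs(best)
}

# Disruption-blind rollout step at mean demand: what a planner believes
# happens when `actions` are applied.
rollout_step <- function(world, actions) {
  advance(world, actions, demand = world$demand_mean, disruption = NULL)
}

#' Discounted action value under the Theory-of-Mind model
#'
#' The value, to `agent`, of the joint action `actions` applied at `world`:
#' the immediate reward of the state reached through a disruption-blind
#' transition, plus `discount` times the value of continuing for
#' `depth_remaining` further steps in which every agent acts per
#' [predicted_joint_action()]. The discount exponent is the planning depth.
#'
#' @param agent Agent name whose reward is evaluated.
#' @param world An `sc_world`.
#' @param actions Integer joint action (one code per agent).
#' @param depth_remaining Number of additional planning steps after this one
#'   (0 gives the one-step value).
#' @param config A [planner_config()].
#' @return The discounted return, in currency units.
#' @export
q_value <- function(agent, world, actions, depth_remaining, config) {
  k <- agent_index(world, agent)
  w2 <- rollout_step(world, actions)
  r <- w2$last_reward[k]
  if (depth_remaining <= 0L) return(r)
  nxt <- predicted_joint_action(agent, w2, depth_remaining - 1L, config)
  r + config$discount * q_value(agent, w2, nxt, depth_remaining - 1L, config)
}

#' Joint action an observer predicts for the next step
#'
#' Non-planning agents contribute their scripted action. Each planning agent,
#' visited once in the world's canonical order, best-responds with the action
#' maximizing its own [q_value()] at the given depth, holding the others at
#' the current iterate. Ties are broken by the fixed action-list order of
#' [action_set()] (proportional before preferential; preferred buyers in
#' declaration order).
#'
#' @param observer Agent name doing the predicting (its model of the others;
#'   models are exact copies here, so the observer only fixes perspective).
#' @param world An `sc_world`.
#' @param depth Remaining planning depth used to evaluate the responses.
#' @param config A [planner_config()].
#' @return Integer joint action vector.
#' @export
predicted_joint_action <- function(observer, world, depth, config) {
  joint <- scripted_joint(world)
  planners <- intersect(world$names, config$tom_agents)
  for (a in planners) {
    k <- agent_index(world, a)
    acts <- action_set(world, a)
    if (length(acts) == 1L) {
      joint[k] <- acts
      next
    }
    best <- acts[1L]
    bestv <- -Inf
    for (act in acts) {
      cand <- joint
      cand[k] <- act
      v <- q_value(a, world, cand, depth, config)
      if (beats(v, bestv, config$tie_tol)) {
        bestv <- v
        best <- act
      }
    }
    joint[k] <- best
  }
  joint
}

#' Choose an agent's action by Theory-of-Mind planning
#'
#' The argmax, over the agent's own action set, of its discounted return over
#' the full horizon, with all other agents predicted by
#' [predicted_joint_action()]. Deterministic given the world; ties go to the
#' first action in canonical order.
#'
#' @param agent Agent name (must be in `config$tom_agents`; agents outside it
#'   bypass the planner and use their scripted rule).
#' @param world An `sc_world`.
#' @param config A [planner_config()].
#' @return The chosen integer action code.
#' @export
choose_action <- function(agent, world, config) {
  if (!agent %in% config$tom_agents) {
    stop("'", agent, "' is not a planning agent; it uses its scripted rule", call. = FALSE)
  }
  k <- agent_index(world, agent)
  acts <- action_set(world, agent)
  if (length(acts) == 1L) return(acts)
  joint <- predicted_joint_action(agent, world, config$horizon - 1L, config)
  best <- acts[1L]
  bestv <- -Inf
  for (act in acts) {
    cand <- joint
    cand[k] <- act
    v <- q_value(agent, world, cand, config$horizon - 1L, config)
    if (beats(v, bestv, config$tie_tol)) {
      bestv <- v
      best <- act
    }
  }
  best
}

# Fast path used by the scenario runner when exactly one agent plans: a
# depth-first search over the planner's own action sequences with everyone
# else scripted. Algebraically identical to choose_action() in that case
# (the sequential best-response pass degenerates to the planner's own
# argmax), but avoids re-advancing each chosen state.
plan_single <- function(world, agent_k, acts, config) {
  discount <- config$discount
  tol <- config$tie_tol
  rec <- function(w, depth) {
    base <- scripted_joint(w)
    bestv <- -Inf
    besta <- acts[1L]
    for (act in acts) {
      j <- base
      j[agent_k] <- act
      w2 <- rollout_step(w, j)
      v <- w2$last_reward[agent_k]
      if (depth > 1L) v <- v + discount * rec(w2, depth - 1L)$value
      if (beats(v, bestv, tol)) {
        bestv <- v
        besta <- act
      }
    }
    list(action = besta, value = bestv)
  }
  rec(world, config$horizon)
}
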