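# World state and the deterministic one-step transition for a multi-echelon
# supply network. State is held in flat numeric arrays indexed by agent so
# the transition is cheap enough to sit inside the planner's rollouts.
#
# Conventions (K agents, lead time L, trust window w):
#   inventory        numeric[K]        on-hand stock
#   owed[s, b]       matrix[K, K]      outstanding orders seller s owes buyer b
#   patient_backlog  numeric[K]        unmet patient demand (healthcenters)
#   pipe[b, s, slot] array[K, K, L]    in-transit shipments; slot 1 arrives at
#                                      the start of the next advance()
#   E_sched[b,s,slot]                  expected deliveries, aligned with pipe
#   Rwin/Ewin[b,s,k] array[K, K, w]    delivery-history window feeding D
#   trust[b, s]      matrix[K, K]      trustworthiness buyer b attributes to s

#' Default world parameters
#'
#' Cost coefficients and structural constants shared by every agent. Units:
#' costs are currency per unit per time-step; rewards currency per unit
#' shipped / patient treated.
#'
#' @param lead_time Shipping lead time between echelons, in time-steps.
#' @param holding_cost Per-unit per-step inventory cost.
#' @param backlog_cost Per-unit per-step backlog cost (must exceed
#'   `holding_cost`, otherwise agents prefer stockouts).
#' @param ship_reward Reward per unit shipped downstream (manufacturers,
#'   distributors).
#' @param treat_reward Reward per patient treated (healthcenters).
#' @param safety_frac Safety stock as a fraction of one step's forecast
#'   demand, entering the order-up-to level.
#' @param delta Trust sensitivity factor in \[0, 1\].
#' @param trust_window Length of the on-time delivery window (default
#'   `lead_time + 1`).
#' @param production_lead Manufacturer production lead time (default 0:
#'   production completes within the step).
#' @param check Validate non-negativity invariants after each transition.
#' @return A named list of parameters.
#' @export
world_params <- function(lead_time = 2L, holding_cost = 1, backlog_cost = 10,
                         ship_reward = 5, treat_reward = 10, safety_frac = 0.5,
                         delta = 0.5, trust_window = lead_time + 1L,
                         production_lead = 0L, check = TRUE) {
  if (backlog_cost <= holding_cost) {
    stop("configuration error: `backlog_cost` must exceed `holding_cost`", call. = FALSE)
  }
  if (delta < 0 || delta > 1) {
    stop("configuration error: `delta` must lie in [0, 1]", call. = FALSE)
  }
  list(
    lead_time = as.integer(lead_time), holding_cost = holding_cost,
    backlog_cost = backlog_cost, ship_reward = ship_reward,
    treat_reward = treat_reward, safety_frac = safety_frac, delta = delta,
    trust_window = as.integer(trust_window),
    production_lead = as.integer(production_lead), check = isTRUE(check)
  )
}

#' Construct a supply-chain world
#'
#' Builds the joint state of all agents, initialized at (approximately) the
#' base-stock steady state implied by the healthcenters' mean demand: full
#' pipelines carrying the steady flow, inventories at their steady post-
#' service level, empty backlogs and trust at its initial value.
#'
#' @param agents Data frame with columns `name`, `echelon` (one of
#'   `"manufacturer"`, `"distributor"`, `"healthcenter"`), optional
#'   `capacity` (units/step; `NA` means unconstrained; ignored for
#'   non-producers), optional `demand` (mean patient demand per step,
#'   healthcenters only), optional `rule` (default decision rule:
#'   `"proportional"`/`"preferential:<buyer>"` for sellers with several
#'   buyers, `"equal"`/`"trust"` for healthcenters with several suppliers).
#' @param edges Data frame with columns `seller`, `buyer` naming the supply
#'   relations.
#' @param params A [world_params()] list.
#' @param trust_init Initial trustworthiness attributed along each supply
#'   edge (default 1).
#' @return An object of class `sc_world`.
#' @examples
#' w <- make_fixture("triad")$world
#' w
#' @export
supply_world <- function(agents, edges, params = world_params(), trust_init = 1) {
  agents <- as.data.frame(agents)
  edges <- as.data.frame(edges)
  stopifnot(all(c("name", "echelon") %in% names(agents)),
            all(c("seller", "buyer") %in% names(edges)))
  if (anyDuplicated(agents$name)) stop("agent names must be unique", call. = FALSE)
  bad <- setdiff(c(edges$seller, edges$buyer), agents$name)
  if (length(bad)) {
    stop("configuration error: unknown agent(s) in edges: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  agents$echelon <- match.arg(agents$echelon,
                              c("manufacturer", "distributor", "healthcenter"),
                              several.ok = TRUE)

  K <- nrow(agents)
  nm <- agents$name
  idx <- setNames(seq_len(K), nm)
  suppliers <- lapply(nm, function(a) unname(idx[edges$seller[edges$buyer == a]]))
  buyers <- lapply(nm, function(a) unname(idx[edges$buyer[edges$seller == a]]))
  is_hc <- agents$echelon == "healthcenter"
  producers <- which(lengths(suppliers) == 0L)
  if (any(is_hc[producers])) {
    stop("configuration error: healthcenters need at least one supplier", call. = FALSE)
  }

  demand <- rep(0, K)
  if (!is.null(agents$demand)) demand[is_hc] <- agents$demand[is_hc]
  if (any(is_hc & demand < 0)) stop("demand must be non-negative", call. = FALSE)

  # steady per-step throughput: healthcenter demand propagated upstream with
  # equal shares across suppliers (trust starts symmetric)
  flow <- demand
  remaining <- setdiff(seq_len(K), which(is_hc))
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(k) {
      all(!buyers[[k]] %in% remaining)
    }, logical(1))]
    if (!length(ready)) stop("supply network contains a cycle", call. = FALSE)
    for (k in ready) {
      flow[k] <- sum(vapply(buyers[[k]], function(b) {
        flow[b] / length(suppliers[[b]])
      }, numeric(1)))
    }
    remaining <- setdiff(remaining, ready)
  }

  capacity <- rep(Inf, K)
  if (!is.null(agents$capacity)) {
    cap <- agents$capacity
    capacity[producers] <- ifelse(is.na(cap[producers]), Inf, cap[producers])
  }

  default_action <- rep(1L, K)
  if (!is.null(agents$rule)) {
    for (k in seq_len(K)) {
      r <- agents$rule[k]
      if (is.na(r) || !nzchar(r)) next
      if (is_hc[k]) {
        default_action[k] <- switch(r, equal = 1L, trust = 2L,
          stop("unknown rule '", r, "' for healthcenter ", nm[k], call. = FALSE))
      } else if (length(buyers[[k]]) > 1L) {
        if (r == "proportional") {
          default_action[k] <- 1L
        } else if (startsWith(r, "preferential:")) {
          pref <- sub("^preferential:", "", r)
          pos <- match(idx[pref], buyers[[k]])
          if (is.na(pos)) stop("preferred buyer '", pref, "' is not a buyer of ", nm[k], call. = FALSE)
          default_action[k] <- 1L + pos
        } else {
          stop("unknown rule '", r, "' for seller ", nm[k], call. = FALSE)
        }
      }
    }
  }

  L <- params$lead_time
  w <- params$trust_window
  pipe <- array(0, dim = c(K, K, L))
  for (b in seq_len(K)) {
    S <- suppliers[[b]]
    if (length(S)) pipe[b, S, ] <- flow[b] / length(S)
  }

  world <- structure(list(
    t = 0L, K = K, names = nm, echelon = agents$echelon, is_hc = is_hc,
    hc_idx = which(is_hc), sellers = which(lengths(buyers) > 0L),
    suppliers = suppliers, buyers = buyers, producers = producers,
    capacity = capacity, demand_mean = demand, steady_flow = flow,
    params = params, default_action = default_action,
    inventory = flow * params$safety_frac,
    owed = matrix(0, K, K, dimnames = list(nm, nm)),
    patient_backlog = rep(0, K),
    pipe = pipe, E_sched = pipe,
    Rwin = array(0, dim = c(K, K, w)), Ewin = array(0, dim = c(K, K, w)),
    trust = matrix(trust_init, K, K, dimnames = list(nm, nm)),
    drate = matrix(1, K, K, dimnames = list(nm, nm)),
    last_demand = flow,
    last_orders = matrix(0, K, K, dimnames = list(nm, nm)),
    last_shipments = matrix(0, K, K, dimnames = list(nm, nm)),
    last_arrivals = matrix(0, K, K, dimnames = list(nm, nm)),
    last_shipped = rep(0, K), last_treated = rep(0, K),
    last_produced = rep(0, K), last_reward = rep(0, K), last_cost = rep(0, K)
  ), class = "sc_world")
  world
}

#' Advance the world by one time-step
#'
#' The deterministic joint transition. Sub-steps, in fixed order:
#' 1. arrivals: pipeline entries due now are added to receiver inventories
#'    and recorded in the delivery windows; trust is updated;
#' 2. production: each producer requests its base-stock quantity and
#'    produces up to its (possibly disrupted) capacity;
#' 3. order placement: each buyer computes its base-stock order from its
#'    inventory position and splits it across suppliers per its split rule;
#'    expectations are registered `lead_time` steps ahead;
#' 4. allocation/shipment: each seller rations on-hand stock over what it
#'    owes its buyers per its allocation rule; shipments enter the pipeline;
#' 5. demand service: healthcenters serve patient demand plus accumulated
#'    patient backlog from inventory;
#' 6. backlog update: unmet orders and demand carry forward;
#' 7. the clock increments.
#'
#' @param world An `sc_world`.
#' @param actions Integer vector, one action code per agent: for sellers with
#'   several buyers 1 = proportional, `1 + i` = preferential to their i-th
#'   buyer; for healthcenters with several suppliers 1 = equal split, 2 =
#'   trust-weighted split; 1 for agents with a single available action. See
#'   [action_set()].
#' @param demand Numeric vector of patient demand per agent this step
#'   (default: the healthcenters' mean demand).
#' @param disruption A [disruption_profile()] or `NULL`. Planners pass `NULL`
#'   (they have no model of disruptions), so their rollouts use nominal
#'   capacity.
#' @return The next `sc_world`, with `last_*` fields describing what happened
#'   during the step (orders, shipments, production, rewards, costs).
#' @export
advance <- function(world, actions, demand = world$demand_mean, disruption = NULL) {
  p <- world$params
  K <- world$K
  L <- p$lead_time
  w <- p$trust_window
  if (length(actions) != K) {
    stop("configuration error: `actions` must contain one action per agent", call. = FALSE)
  }
  inv <- world$inventory
  owed <- world$owed
  pb <- world$patient_backlog
  pipe <- world$pipe
  Es <- world$E_sched

  ## 1. arrivals + trust bookkeeping ----------------------------------------
  arr <- pipe[, , 1L]
  inv <- inv + .rowSums(arr, K, K)
  Enow <- Es[, , 1L]
  if (L > 1L) {
    pipe[, , seq_len(L - 1L)] <- pipe[, , 2:L]
    Es[, , seq_len(L - 1L)] <- Es[, , 2:L]
  }
  pipe[, , L] <- 0
  Es[, , L] <- 0

  Rw <- world$Rwin
  Ew <- world$Ewin
  if (w > 1L) {
    Rw[, , seq_len(w - 1L)] <- Rw[, , 2:w]
    Ew[, , seq_len(w - 1L)] <- Ew[, , 2:w]
  }
  Rw[, , w] <- arr
  Ew[, , w] <- Enow
  ratio <- pmin.int(Rw / Ew, 1)
  ratio[Ew == 0] <- 1
  drate <- matrix(.rowMeans(ratio, K * K, w), K, K)
  trust <- (1 - p$delta) * world$trust + p$delta * drate

  ## 2. production -----------------------------------------------------------
  produced <- numeric(K)
  up_prod <- p$production_lead + 1 + p$safety_frac
  for (k in world$producers) {
    req <- world$last_demand[k] * up_prod - (inv[k] - sum(owed[k, ]))
    if (req < 0) req <- 0
    cap <- world$capacity[k]
    if (!is.null(disruption) && world$names[k] == disruption$target) {
      cap <- effective_capacity(cap, disruption, world$t)
    }
    produced[k] <- if (req < cap) req else cap
    inv[k] <- inv[k] + produced[k]
  }

  ## 3. order placement ------------------------------------------------------
  orders <- matrix(0, K, K)
  up_buy <- L + 1 + p$safety_frac
  is_hc <- world$is_hc
  for (b in seq_len(K)) {
    S <- world$suppliers[[b]]
    nS <- length(S)
    if (!nS) next
    # position counts only what has actually shipped (in transit); orders a
    # supplier has failed to fill are re-ordered, amplifying upstream demand
    on_order <- sum(pipe[b, , ])
    backlog_b <- if (is_hc[b]) pb[b] else sum(owed[b, ])
    q <- world$last_demand[b] * up_buy - (inv[b] + on_order - backlog_b)
    if (q < 0) q <- 0
    if (nS == 1L) {
      orders[b, S] <- q
    } else if (is_hc[b] && actions[b] == 2L) {
      tv <- trust[b, S]
      st <- sum(tv)
      orders[b, S] <- if (st > 0) q * tv / st else q / nS
    } else {
      orders[b, S] <- q / nS
    }
  }
  # orders are standing requirements: each buyer restates its whole current
  # deficit, so unmet demand rolls forward (and re-routes) rather than being
  # double-billed against the seller
  towed <- t.default(orders)
  owed <- towed
  Es[, , L] <- Es[, , L] + orders
  last_demand <- world$last_demand
  sellers <- world$sellers
  last_demand[sellers] <- .rowSums(towed, K, K)[sellers]

  ## 4. allocation / shipment ------------------------------------------------
  ship <- matrix(0, K, K)
  shipped <- numeric(K)
  for (s in sellers) {
    B <- world$buyers[[s]]
    req <- owed[s, B]
    oh <- inv[s]
    tot <- sum(req)
    if (tot <= oh || length(B) == 1L) {
      sh <- if (tot <= oh) req else req * (oh / tot)
    } else if (actions[s] == 1L) {
      sh <- req * (oh / tot)
    } else {
      sh <- req * 0
      ord <- actions[s] - 1L
      ord <- c(ord, seq_along(B)[-ord])
      rem <- oh
      for (i in ord) {
        sh[i] <- if (rem < req[i]) rem else req[i]
        rem <- rem - sh[i]
      }
    }
    inv[s] <- oh - sum(sh)
    owed[s, B] <- req - sh
    pipe[cbind(B, s, L)] <- pipe[cbind(B, s, L)] + sh
    ship[s, B] <- sh
    shipped[s] <- sum(sh)
  }

  ## 5/6. patient demand service + backlog update -----------------------------
  treated <- numeric(K)
  for (b in world$hc_idx) {
    need <- demand[b] + pb[b]
    served <- if (inv[b] < need) inv[b] else need
    inv[b] <- inv[b] - served
    pb[b] <- need - served
    treated[b] <- served
    last_demand[b] <- demand[b]
  }

  backlog <- .rowSums(owed, K, K) + pb
  cost <- p$holding_cost * inv + p$backlog_cost * backlog
  bonus <- p$ship_reward * shipped
  bonus[world$hc_idx] <- p$treat_reward * treated[world$hc_idx]
  reward <- bonus - cost

  if (p$check) {
    if (min(inv, owed, pb, pipe, orders, produced) < -1e-9) {
      stop("invariant violation: negative quantity after transition", call. = FALSE)
    }
  }

  world$t <- world$t + 1L
  world$inventory <- inv
  world$owed <- owed
  world$patient_backlog <- pb
  world$pipe <- pipe
  world$E_sched <- Es
  world$Rwin <- Rw
  world$Ewin <- Ew
  world$trust <- trust
  world$drate <- drate
  world$last_demand <- last_demand
  world$last_orders <- orders
  world$last_shipments <- ship
  world$last_arrivals <- arr
  world$last_shipped <- shipped
  world$last_treated <- treated
  world$last_produced <- produced
  world$last_reward <- reward
  world$last_cost <- cost
  world
}

#' Per-step reward of one agent
#'
#' Manufacturers and distributors earn `ship_reward` per unit shipped and pay
#' holding and backlog costs; healthcenters earn `treat_reward` per patient
#' treated and pay holding and backlog costs (patient backlog priced at the
#' same rate as order backlog).
#'
#' @param agent Agent name.
#' @param world An `sc_world` in its post-transition state.
#' @param shipped Units shipped by the agent this step (default: taken from
#'   the world's `last_shipped`).
#' @param treated Patients treated this step (default: from `last_treated`).
#' @param costs Cost parameters (default: the world's own).
#' @return The scalar reward in currency units.
#' @export
step_reward <- function(agent, world, shipped = NULL, treated = NULL,
                        costs = world$params) {
  k <- agent_index(world, agent)
  if (is.null(shipped)) shipped <- world$last_shipped[k]
  if (is.null(treated)) treated <- world$last_treated[k]
  backlog <- sum(world$owed[k, ]) + world$patient_backlog[k]
  base <- -costs$holding_cost * world$inventory[k] - costs$backlog_cost * backlog
  if (world$is_hc[k]) base + costs$treat_reward * treated
  else base + costs$ship_reward * shipped
}

#' Available actions of an agent
#'
#' Manufacturers (and any agent with at most one buyer and one supplier)
#' have a single action. Sellers with `m > 1` buyers choose among
#' proportional allocation and `m` preferential allocations, in that fixed
#' order. Healthcenters with several suppliers choose between equal and
#' trust-weighted order splitting.
#'
#' @param world An `sc_world`.
#' @param agent Agent name.
#' @return Integer vector of action codes, in canonical (tie-break) order.
#' @export
action_set <- function(world, agent) {
  k <- agent_index(world, agent)
  nb <- length(world$buyers[[k]])
  if (world$is_hc[k]) {
    if (length(world$suppliers[[k]]) > 1L) c(1L, 2L) else 1L
  } else if (nb > 1L) {
    seq_len(1L + nb)
  } else {
    1L
  }
}

#' Human-readable label of an action code
#'
#' @inheritParams action_set
#' @param code Integer action code as used by [advance()].
#' @return A string such as `"proportional"`, `"preferential:Equal HC"`,
#'   `"equal"` or `"trust"`.
#' @export
action_label <- function(world, agent, code) {
  k <- agent_index(world, agent)
  if (world$is_hc[k]) {
    if (length(world$suppliers[[k]]) > 1L) c("equal", "trust")[code] else "fixed"
  } else if (length(world$buyers[[k]]) > 1L) {
    if (code == 1L) "proportional"
    else paste0("preferential:", world$names[world$buyers[[k]][code - 1L]])
  } else if (length(world$buyers[[k]]) == 1L) {
    "ship"
  } else {
    "produce"
  }
}

# The scripted joint action: every agent's configured default rule.
scripted_joint <- function(world) world$default_action

agent_index <- function(world, agent) {
  if (is.numeric(agent)) return(as.integer(agent))
  k <- match(agent, world$names)
  if (is.na(k)) {
    stop("configuration error: unknown agent '", agent, "'", call. = FALSE)
  }
  k
}

#' @export
print.sc_world <- function(x, ...) {
  cat(sprintf("<sc_world> t = %d, %d agents (lead time %d)\n",
              x$t, x$K, x$params$lead_time))
  df <- data.frame(
    agent = x$names, echelon = x$echelon,
    inventory = round(x$inventory, 3),
    backlog = round(rowSums(x$owed) + x$patient_backlog, 3),
    capacity = x$capacity
  )
  print(df, row.names = FALSE)
  invisible(x)
}
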