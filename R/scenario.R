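# Scenario orchestration: the six-agent study network, warm-up detection,
# disruption scheduling, full runs with tidy trace capture, cost accounting
# and sensitivity sweeps over the trust factor.

.default_delta_grid <- c(0.025, 0.05, 0.2, 0.4, 0.5)

#' Configure a simulation scenario
#'
#' Returns a fully explicit configuration for [run_scenario()]. The five
#' named scenarios cover the study grid: S1 (no planning, short disruption,
#' delta = 0.5), S2 (Disrupted DS plans, short, 0.5), S3 (planning, short,
#' delta sweep), S4 (planning, long, delta sweep) and S5 (planning, moderate,
#' 0.5). In every named scenario "Trust HC" splits orders by trustworthiness
#' and "Equal HC" splits equally; set `split_rules` to make both equal for
#' the comparison baseline.
#'
#' @param scenario One of `"S1"`..`"S5"` or `"custom"`.
#' @param ... Overrides for any configuration field: `demand` (list with
#'   `type = "constant"` and `value`, or `type = "normal"` with `mean`, `sd`,
#'   `seed`), `lead_time`, `holding_cost`, `backlog_cost`, `ship_reward`,
#'   `treat_reward`, `safety_frac`, `capacity_factor` (nominal manufacturer
#'   capacity as a multiple of steady-state production), `delta`,
#'   `delta_grid`, `trust_window`, `horizon`, `discount`, `tom` (logical:
#'   does "Disrupted DS" plan), `split_rules` (named character vector for the
#'   healthcenters), `disruption` (profile name or list with `severity`,
#'   `breadth`), `stab_tol`, `stab_patience`, `onset_offset`, `max_warmup`,
#'   `total_after_onset` (accounting window after onset; default `4 *
#'   breadth`, i.e. the disruption plus a tail of three breadths).
#' @return A list of class `sc_config` with every default made explicit.
#' @examples
#' cfg <- scenario_config("S1")
#' cfg$disruption
#' @export
scenario_config <- function(scenario = c("custom", "S1", "S2", "S3", "S4", "S5"), ...) {
  scenario <- match.arg(toupper(scenario[1]),
                        c("CUSTOM", "S1", "S2", "S3", "S4", "S5"))
  scenario <- if (scenario == "CUSTOM") "custom" else scenario
  cfg <- list(
    scenario = scenario,
    demand = list(type = "constant", value = 100),
    lead_time = 2L,
    holding_cost = 1, backlog_cost = 10, ship_reward = 5, treat_reward = 10,
    safety_frac = 0.5,
    capacity_factor = 1.1,
    delta = 0.5,
    delta_grid = .default_delta_grid,
    trust_window = NULL, # defaults to lead_time + 1
    horizon = 6L, discount = 0.9, tie_tol = 0.02,
    tom = FALSE,
    split_rules = c("Trust HC" = "trust", "Equal HC" = "equal"),
    disruption = "short",
    stab_tol = 1e-6, stab_patience = 5L, onset_offset = 5L, max_warmup = 80L,
    total_after_onset = NULL
  )
  preset <- switch(scenario,
    S1 = list(tom = FALSE, disruption = "short", delta = 0.5),
    S2 = list(tom = TRUE, disruption = "short", delta = 0.5),
    S3 = list(tom = TRUE, disruption = "short", delta_grid = .default_delta_grid),
    S4 = list(tom = TRUE, disruption = "long", delta_grid = .default_delta_grid),
    S5 = list(tom = TRUE, disruption = "moderate", delta = 0.5),
    list()
  )
  cfg <- modifyList(cfg, preset)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("configuration error: unknown key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- modifyList(cfg, dots)
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$trust_window)) cfg$trust_window <- cfg$lead_time + 1L
  if (cfg$delta < 0 || cfg$delta > 1) {
    stop("configuration error: key `delta` must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$delta_grid < 0 | cfg$delta_grid > 1)) {
    stop("configuration error: key `delta_grid` must lie in [0, 1]", call. = FALSE)
  }
  if (!all(sort(names(cfg$split_rules)) == c("Equal HC", "Trust HC"))) {
    stop("configuration error: key `split_rules` must name 'Trust HC' and 'Equal HC'",
         call. = FALSE)
  }
  if (!all(cfg$split_rules %in% c("trust", "equal"))) {
    stop("configuration error: key `split_rules` values must be 'trust' or 'equal'",
         call. = FALSE)
  }
  d <- cfg$demand
  if (!d$type %in% c("constant", "normal")) {
    stop("configuration error: key `demand$type` must be 'constant' or 'normal'",
         call. = FALSE)
  }
  if (d$type == "normal") {
    if (is.null(d$mean) || d$mean <= 0) {
      stop("configuration error: key `demand$mean` must be > 0", call. = FALSE)
    }
    if (is.null(d$sd) || d$sd < 0) {
      stop("configuration error: key `demand$sd` must be >= 0", call. = FALSE)
    }
  } else if (is.null(d$value) || d$value < 0) {
    stop("configuration error: key `demand$value` must be >= 0", call. = FALSE)
  }
  if (is.character(cfg$disruption)) {
    cfg$disruption <- disruption_profile(cfg$disruption)
  } else if (is.list(cfg$disruption) && !inherits(cfg$disruption, "disruption_profile")) {
    cfg$disruption <- disruption_profile(severity = cfg$disruption$severity,
                                         breadth = cfg$disruption$breadth)
  }
  structure(cfg, class = "sc_config")
}

#' The six-agent study network
#'
#' Two manufacturers, two distributors and two healthcenters. Each
#' distributor is supplied by exactly one manufacturer ("Disrupted DS" by
#' "Disrupted MN", "Not-Disrupted DS" by "Not-Disrupted MN"); both
#' healthcenters order from both distributors. Nominal manufacturer capacity
#' is `capacity_factor` times steady-state production.
#'
#' @param config An [scenario_config()].
#' @return An `sc_world` initialized at the base-stock steady state.
#' @export
build_network <- function(config) {
  d <- demand_mean(config)
  agents <- data.frame(
    name = c("Disrupted MN", "Not-Disrupted MN", "Disrupted DS",
             "Not-Disrupted DS", "Equal HC", "Trust HC"),
    echelon = c("manufacturer", "manufacturer", "distributor", "distributor",
                "healthcenter", "healthcenter"),
    capacity = c(config$capacity_factor * d, config$capacity_factor * d,
                 NA, NA, NA, NA),
    demand = c(NA, NA, NA, NA, d, d),
    rule = c("", "", "proportional", "proportional",
             unname(config$split_rules["Equal HC"]),
             unname(config$split_rules["Trust HC"]))
  )
  edges <- data.frame(
    seller = c("Disrupted MN", "Not-Disrupted MN",
               "Disrupted DS", "Disrupted DS",
               "Not-Disrupted DS", "Not-Disrupted DS"),
    buyer = c("Disrupted DS", "Not-Disrupted DS",
              "Equal HC", "Trust HC", "Equal HC", "Trust HC")
  )
  params <- world_params(
    lead_time = config$lead_time, holding_cost = config$holding_cost,
    backlog_cost = config$backlog_cost, ship_reward = config$ship_reward,
    treat_reward = config$treat_reward, safety_frac = config$safety_frac,
    delta = config$delta, trust_window = config$trust_window
  )
  supply_world(agents, edges, params)
}

demand_mean <- function(config) {
  if (config$demand$type == "constant") config$demand$value else config$demand$mean
}

#' Generate a patient demand stream
#'
#' @param spec Demand specification: `list(type = "constant", value = )` or
#'   `list(type = "normal", mean = , sd = , seed = )`. Normal draws are
#'   truncated at zero.
#' @param length Number of time-steps.
#' @param seed Optional integer seed overriding `spec$seed`; the stream is
#'   reproducible given the seed.
#' @return Numeric vector of per-step demand for one healthcenter.
#' @examples
#' generate_demand(list(type = "constant", value = 100), 5)
#' @export
generate_demand <- function(spec, length, seed = NULL) {
  length <- as.integer(length)
  if (spec$type == "constant") return(rep(spec$value, length))
  if (spec$sd < 0) stop("configuration error: `sd` must be >= 0", call. = FALSE)
  seed <- if (!is.null(seed)) seed else spec$seed
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  pmax(0, rnorm(length, spec$mean, spec$sd))
}

# Relative change between consecutive observations, guarded near zero.
rel_change <- function(now, prev) abs(now - prev) / pmax(abs(prev), 1)

#' Detect warm-up stabilization in a run trace
#'
#' The supply chain is considered stabilized at the first step `t` such that
#' every order and shipment series changes by less than `tolerance`
#' (relative) for `patience` consecutive steps starting at `t`.
#'
#' @param trace A trace tibble as produced by [run_scenario()] (one row per
#'   time-step and agent, with `order_placed` and `shipped` columns).
#' @param tolerance Relative change threshold (default `1e-6`).
#' @param patience Number of consecutive quiet steps required (default 5).
#' @return The stabilization time-step.
#' @export
detect_stabilization <- function(trace, tolerance = 1e-6, patience = 5L) {
  wide <- trace[, c("t", "agent", "order_placed", "shipped")]
  ts <- sort(unique(wide$t))
  if (length(ts) < patience + 1L) {
    stop("trace must cover at least `patience` + 1 steps", call. = FALSE)
  }
  mat <- cbind(
    matrix(wide$order_placed, nrow = length(ts), byrow = TRUE),
    matrix(wide$shipped, nrow = length(ts), byrow = TRUE)
  )
  agents <- unique(wide$agent)
  colnames(mat) <- c(paste0("order_placed:", agents), paste0("shipped:", agents))
  quiet <- rel_change(mat[-1, , drop = FALSE], mat[-nrow(mat), , drop = FALSE]) < tolerance
  all_quiet <- apply(quiet, 1, all)
  run <- 0L
  for (i in seq_along(all_quiet)) {
    run <- if (all_quiet[i]) run + 1L else 0L
    # stabilized once `patience` consecutive quiet steps have been observed
    if (run >= patience) return(ts[i + 1L])
  }
  worst <- colnames(mat)[which.max(rel_change(mat[nrow(mat), ], mat[nrow(mat) - 1L, ]))]
  stop("no stabilization within the trace; still-moving series include: ", worst,
       call. = FALSE)
}

#' Run a full scenario
#'
#' Simulates warm-up until the ordering and shipping levels are constant,
#' schedules the disruption `onset_offset` steps later, and continues through
#' the disruption plus its aftermath (by default three breadths). Fully
#' deterministic under constant demand.
#'
#' @param config An [scenario_config()].
#' @param keep_world Keep the final `sc_world` in the result (default TRUE).
#' @return An object of class `sc_run` with elements `trace` (tibble, one row
#'   per time-step and agent), `flows` (tibble, one row per time-step and
#'   supply edge: orders, shipments, arrivals), `trust` (tibble, one row per
#'   time-step and buyer-supplier pair), `config`, `onset`, `stabilized_at`,
#'   `window` (cost accounting window) and `disruption`.
#' @examples
#' \donttest{
#' run <- run_scenario(scenario_config("S1"))
#' glance(run)
#' }
#' @export
run_scenario <- function(config, keep_world = TRUE) {
  config <- validate_config(config)
  world <- build_network(config)
  profile <- config$disruption
  after <- if (is.null(config$total_after_onset)) 4L * profile$breadth
           else as.integer(config$total_after_onset)
  n_max <- config$max_warmup + config$onset_offset + after + 1L
  dem_hc <- generate_demand(config$demand, n_max)
  pcfg <- planner_config(config$horizon, config$discount,
                         tom_agents = if (config$tom) "Disrupted DS" else character(),
                         tie_tol = config$tie_tol)

  K <- world$K
  hc <- which(world$is_hc)
  edge_s <- rep(seq_len(K), lengths(world$buyers))
  edge_b <- unlist(world$buyers)
  trust_pairs <- do.call(rbind, lapply(which(lengths(world$suppliers) > 1L), function(b) {
    cbind(b = b, s = world$suppliers[[b]])
  }))

  rows <- vector("list", n_max)
  frows <- vector("list", n_max)
  trows <- vector("list", n_max)
  series <- matrix(NA_real_, n_max, 2L * K) # orders placed + shipped, per agent
  stabilized_at <- NA_integer_
  onset <- NA_integer_
  end_t <- n_max
  ds_k <- agent_index(world, "Disrupted DS")
  ds_acts <- action_set(world, "Disrupted DS")

  step <- 0L
  while (step < end_t) {
    step <- step + 1L
    actions <- scripted_joint(world)
    if (config$tom && length(ds_acts) > 1L) {
      actions[ds_k] <- plan_single(world, ds_k, ds_acts, pcfg)$action
    }
    demand_t <- numeric(K)
    demand_t[hc] <- dem_hc[step]
    world <- advance(world, actions, demand = demand_t, disruption = profile)
    tnow <- world$t

    rows[[step]] <- tibble::tibble(
      t = tnow, agent = world$names, echelon = world$echelon,
      action = vapply(seq_len(K), function(k) action_label(world, k, actions[k]),
                      character(1)),
      inventory = world$inventory,
      order_backlog = rowSums(world$owed),
      patient_backlog = world$patient_backlog,
      backlog = rowSums(world$owed) + world$patient_backlog,
      order_placed = rowSums(world$last_orders),
      order_received = colSums(world$last_orders),
      shipped = world$last_shipped,
      produced = world$last_produced,
      treated = world$last_treated,
      demand = demand_t,
      reward = world$last_reward,
      cost = world$last_cost
    )
    frows[[step]] <- tibble::tibble(
      t = tnow,
      seller = world$names[edge_s],
      buyer = world$names[edge_b],
      order = world$last_orders[cbind(edge_b, edge_s)],
      shipment = world$last_shipments[cbind(edge_s, edge_b)],
      arrival = world$last_arrivals[cbind(edge_b, edge_s)]
    )
    if (!is.null(trust_pairs)) {
      trows[[step]] <- tibble::tibble(
        t = tnow,
        buyer = world$names[trust_pairs[, "b"]],
        seller = world$names[trust_pairs[, "s"]],
        trust = world$trust[trust_pairs],
        on_time_rate = world$drate[trust_pairs]
      )
    }
    series[step, ] <- c(rowSums(world$last_orders), world$last_shipped)

    if (is.na(stabilized_at) && step > config$stab_patience) {
      win <- series[(step - config$stab_patience):step, , drop = FALSE]
      ch <- rel_change(win[-1, , drop = FALSE], win[-nrow(win), , drop = FALSE])
      if (all(ch < config$stab_tol)) {
        stabilized_at <- tnow
        onset <- tnow + config$onset_offset
        profile$start <- onset
        end_t <- step + config$onset_offset + after
        if (end_t > n_max) end_t <- n_max
      } else if (step >= config$max_warmup) {
        worst <- which.max(ch[nrow(ch), ])
        lab <- c(paste0("orders placed by ", world$names),
                 paste0("shipments by ", world$names))[worst]
        stop("supply chain did not stabilize within `max_warmup` steps; ",
             "still-moving series include: ", lab, call. = FALSE)
      }
    }
  }
  if (is.na(stabilized_at)) {
    stop("supply chain did not stabilize within `max_warmup` steps", call. = FALSE)
  }

  structure(list(
    trace = dplyr::bind_rows(rows[seq_len(step)]),
    flows = dplyr::bind_rows(frows[seq_len(step)]),
    trust = dplyr::bind_rows(trows[seq_len(step)]),
    config = config,
    disruption = profile,
    stabilized_at = stabilized_at,
    onset = onset,
    window = c(start = onset, end = world$t),
    world = if (keep_world) world else NULL
  ), class = "sc_run")
}

#' Accumulated holding-plus-backlog cost of an agent
#'
#' Sums `holding_cost * inventory + backlog_cost * backlog` over a window of
#' the trace. Shipping and treatment reward bonuses are deliberately
#' excluded: this is the cost metric used for scenario comparisons.
#'
#' @param run An `sc_run` (or its trace tibble).
#' @param agents Agent names (default: all agents).
#' @param window Integer vector `c(start, end)` of time-steps, inclusive;
#'   default: from disruption onset to the end of the run.
#' @return A tibble with columns `agent` and `cost`.
#' @export
agent_cost <- function(run, agents = NULL, window = NULL) {
  trace <- if (inherits(run, "sc_run")) run$trace else run
  if (is.null(window) && inherits(run, "sc_run")) window <- run$window
  if (is.null(window)) window <- range(trace$t)
  if (is.null(agents)) agents <- unique(trace$agent)
  trace |>
    dplyr::filter(.data$t >= window[1], .data$t <= window[2],
                  .data$agent %in% agents) |>
    dplyr::group_by(agent = .data$agent) |>
    dplyr::summarise(cost = sum(.data$cost), .groups = "drop")
}

#' Percent cost change of a scenario against its baseline
#'
#' For each agent, `100 * (cost_scenario - cost_baseline) / cost_baseline`
#' over the window from disruption onset to the end of the run, plus an
#' `"Overall Supply Chain"` row summing all agents. Both runs must share
#' their configuration apart from the healthcenters' split rules.
#'
#' @param run The scenario `sc_run`.
#' @param baseline The baseline `sc_run` (typically both healthcenters
#'   splitting equally).
#' @return A tibble with columns `agent`, `cost`, `baseline_cost`,
#'   `change_pct` (NA where the baseline cost is zero).
#' @export
cost_change_vs_baseline <- function(run, baseline) {
  a <- agent_cost(run)
  b <- agent_cost(baseline) |> dplyr::rename(baseline_cost = "cost")
  out <- dplyr::inner_join(a, b, by = "agent")
  out <- dplyr::bind_rows(
    out,
    tibble::tibble(agent = "Overall Supply Chain",
                   cost = sum(a$cost), baseline_cost = sum(b$baseline_cost))
  )
  out$change_pct <- ifelse(out$baseline_cost == 0, NA_real_,
                           100 * (out$cost - out$baseline_cost) / out$baseline_cost)
  out
}

#' Sweep the trust sensitivity factor
#'
#' Re-runs a scenario for each value of `delta`, all other settings fixed.
#'
#' @param config An [scenario_config()].
#' @param deltas Numeric vector of sensitivity values in \[0, 1\] (default:
#'   the configuration's `delta_grid`).
#' @return An object of class `sc_sweep`: a tibble with one row per `delta`
#'   and agent, columns `delta`, `agent`, `echelon`, `cost`.
#' @export
sweep_delta <- function(config, deltas = config$delta_grid) {
  if (any(deltas < 0 | deltas > 1)) {
    stop("configuration error: `deltas` must lie in [0, 1]", call. = FALSE)
  }
  res <- purrr::map_dfr(deltas, function(d) {
    cfg <- modifyList(config, list(delta = d))
    class(cfg) <- "sc_config"
    run <- run_scenario(cfg, keep_world = FALSE)
    costs <- agent_cost(run)
    ech <- run$trace |> dplyr::distinct(.data$agent, .data$echelon)
    dplyr::left_join(costs, ech, by = "agent") |>
      dplyr::mutate(delta = d, .before = 1)
  })
  class(res) <- c("sc_sweep", class(res))
  res
}

#' @export
print.sc_config <- function(x, ...) {
  cat(sprintf("<sc_config> scenario %s: ToM %s, disruption %s, delta %g\n",
              x$scenario, if (x$tom) "yes" else "no",
              if (inherits(x$disruption, "disruption_profile")) x$disruption$type
              else as.character(x$disruption), x$delta))
  cat(sprintf("  demand %s, lead time %d, horizon %d, discount %g\n",
              if (x$demand$type == "constant") sprintf("constant %g", x$demand$value)
              else sprintf("normal(%g, %g)", x$demand$mean, x$demand$sd),
              x$lead_time, x$horizon, x$discount))
  invisible(x)
}

#' @export
print.sc_run <- function(x, ...) {
  cat(sprintf("<sc_run> scenario %s: %d steps, onset %d (stabilized at %d), disruption %s\n",
              x$config$scenario, max(x$trace$t), x$onset, x$stabilized_at,
              x$disruption$type))
  print(agent_cost(x), ...)
  invisible(x)
}
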