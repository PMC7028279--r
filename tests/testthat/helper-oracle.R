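# Brute-force planning oracle: exhaustive search over the planning agent's
# own action sequences, with every other agent following its scripted rule
# through the same disruption-blind rollout. Independent of the recursive
# planner implementation.
brute_force_plan <- function(world, agent, horizon, discount, tie_tol = 0) {
  k <- pharmsim:::agent_index(world, agent)
  acts <- action_set(world, agent)
  seqs <- expand.grid(rep(list(acts), horizon))
  best_val <- -Inf
  best_first <- acts[1L]
  # row order of expand.grid enumerates the first step fastest; iterate in an
  # order that visits first-step actions in canonical order for tie-breaks
  seqs <- seqs[do.call(order, as.list(seqs)), , drop = FALSE]
  for (i in seq_len(nrow(seqs))) {
    w <- world
    val <- 0
    for (h in seq_len(horizon)) {
      j <- pharmsim:::scripted_joint(w)
      j[k] <- seqs[i, h]
      w <- advance(w, j, demand = w$demand_mean, disruption = NULL)
      val <- val + discount^(h - 1) * w$last_reward[k]
    }
    if (!is.finite(best_val) || val > best_val + tie_tol * abs(best_val)) {
      best_val <- val
      best_first <- seqs[i, 1L]
    }
  }
  list(action = best_first, value = best_val)
}

run_steps <- function(world, n, actions = NULL, demand = NULL, disruption = NULL) {
  for (i in seq_len(n)) {
    a <- if (is.null(actions)) world$default_action else actions
    d <- if (is.null(demand)) world$demand_mean else demand
    world <- advance(world, a, demand = d, disruption = disruption)
  }
  world
}
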