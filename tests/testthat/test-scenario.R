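test_that("demand streams are reproducible and respect their spec", {
  expect_equal(generate_demand(list(type = "constant", value = 100), 5), rep(100, 5))
  expect_equal(generate_demand(list(type = "normal", mean = 100, sd = 0, seed = 1), 4),
               rep(100, 4))
  d1 <- generate_demand(list(type = "normal", mean = 100, sd = 10), 50, seed = 8)
  d2 <- generate_demand(list(type = "normal", mean = 100, sd = 10), 50, seed = 8)
  expect_identical(d1, d2)
  expect_true(all(d1 >= 0))
  d3 <- generate_demand(list(type = "normal", mean = 5, sd = 50), 200, seed = 8)
  expect_true(all(d3 >= 0)) # truncation at zero
  expect_error(generate_demand(list(type = "normal", mean = 100, sd = -1), 5, seed = 1),
               "sd")
})

test_that("stabilization is detected once orders and shipments settle", {
  cfg <- scenario_config("S1", total_after_onset = 20L)
  run <- run_scenario(cfg)
  # the network is initialized at its steady state, so the runner detects
  # stabilization as soon as `patience` quiet steps have been seen
  expect_equal(run$stabilized_at, cfg$stab_patience + 1L)
  expect_equal(run$onset, run$stabilized_at + cfg$onset_offset)
  expect_equal(detect_stabilization(run$trace), run$stabilized_at)
  # post-onset the series move again: a trace starting at onset does not pass
  expect_error(
    detect_stabilization(dplyr::filter(run$trace, t >= run$onset - 1),
                         patience = 15),
    "no stabilization"
  )
  expect_error(detect_stabilization(run$trace[run$trace$t < 4, ], patience = 5),
               "at least")
})

test_that("a run that cannot stabilize fails with a diagnostic", {
  cfg <- scenario_config("S1", demand = list(type = "normal", mean = 100, sd = 20, seed = 2),
                         stab_tol = 0, max_warmup = 12L)
  expect_error(run_scenario(cfg), "did not stabilize")
})

test_that("window costs accumulate holding and backlog terms only", {
  cfg <- scenario_config("S1", total_after_onset = 20L)
  run <- run_scenario(cfg)
  p <- c(holding = cfg$holding_cost, backlog = cfg$backlog_cost)
  tr <- run$trace
  expect_equal(tr$cost, p[["holding"]] * tr$inventory + p[["backlog"]] * tr$backlog)
  byhand <- tr |>
    dplyr::filter(t >= run$window[1], t <= run$window[2], agent == "Equal HC")
  expect_equal(agent_cost(run, agents = "Equal HC")$cost, sum(byhand$cost))
  # zero inventory and backlog throughout means zero cost
  empty <- tibble::tibble(t = 1:5, agent = "X", cost = 0)
  expect_equal(agent_cost(empty, window = c(1, 5))$cost, 0)
})

test_that("cost changes against a baseline follow the standard relative formula", {
  cfg <- scenario_config("S1", total_after_onset = 15L)
  run <- run_scenario(cfg)
  cc <- cost_change_vs_baseline(run, run)
  expect_true(all(cc$change_pct == 0))
  doubled <- run
  doubled$trace$cost <- 2 * doubled$trace$cost
  cc2 <- cost_change_vs_baseline(doubled, run)
  expect_true(all(abs(cc2$change_pct - 100) < 1e-9))
  expect_equal(cc2$agent[nrow(cc2)], "Overall Supply Chain")
  expect_equal(cc2$cost[nrow(cc2)], sum(agent_cost(doubled)$cost))
})

test_that("without a disruption the equal-splitting network is symmetric", {
  cfg <- scenario_config("custom",
                         split_rules = c("Trust HC" = "equal", "Equal HC" = "equal"),
                         disruption = list(severity = 0, breadth = 10))
  run <- run_scenario(cfg)
  hc <- run$trace |> dplyr::filter(agent %in% c("Trust HC", "Equal HC"))
  wide <- tidyr::pivot_wider(hc[, c("t", "agent", "cost")],
                             names_from = "agent", values_from = "cost")
  expect_equal(wide$`Trust HC`, wide$`Equal HC`)
  expect_true(all(run$trust$trust == 1))
})

test_that("the S1 scenario never uses preferential allocation", {
  run <- run_scenario(scenario_config("S1", total_after_onset = 20L))
  expect_equal(unique(run$trace$action[run$trace$agent == "Disrupted DS"]),
               "proportional")
})

test_that("sweeping a single delta reproduces the plain scenario run", {
  cfg <- scenario_config("S1", total_after_onset = 15L)
  sw <- sweep_delta(cfg, deltas = 0.5)
  run <- run_scenario(cfg)
  costs <- agent_cost(run)
  merged <- dplyr::inner_join(tibble::as_tibble(sw), costs, by = "agent",
                              suffix = c("_sweep", "_run"))
  expect_equal(merged$cost_sweep, merged$cost_run)
  expect_error(sweep_delta(cfg, deltas = c(0.2, 1.2)), "deltas")
})

test_that("tidiers expose traces and run summaries", {
  run <- run_scenario(scenario_config("S1", total_after_onset = 10L))
  expect_s3_class(tidy(run), "tbl_df")
  expect_equal(tidy(run, "trust"), run$trust)
  g <- glance(run)
  expect_equal(nrow(g), 1)
  expect_equal(g$scenario, "S1")
  expect_equal(g$overall_cost, sum(agent_cost(run)$cost))
})

test_that("plots build without evaluation errors", {
  run <- run_scenario(scenario_config("S1", total_after_onset = 10L))
  expect_s3_class(ggplot2::ggplot_build(autoplot(run)), "ggplot_built")
  expect_s3_class(ggplot2::ggplot_build(plot_trust(run)), "ggplot_built")
  expect_s3_class(ggplot2::ggplot_build(plot_orders(run, "Trust HC")), "ggplot_built")
  sw <- sweep_delta(scenario_config("S1", total_after_onset = 10L), deltas = c(0.2, 0.5))
  expect_s3_class(ggplot2::ggplot_build(autoplot(sw)), "ggplot_built")
})
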