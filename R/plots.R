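# ggplot2 views of runs and sweeps: per-agent time series, trust
# trajectories, per-edge order flows and delta-sweep cost curves.

#' Plot a scenario run
#'
#' Faceted time series of per-agent state variables, with the disruption
#' window shaded.
#'
#' @param object An `sc_run`.
#' @param vars Trace columns to plot (default inventory, backlog, orders
#'   placed).
#' @param agents Agents to include (default all).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sc_run <- function(object, vars = c("inventory", "backlog", "order_placed"),
                            agents = NULL, ...) {
  df <- object$trace
  if (!is.null(agents)) df <- dplyr::filter(df, .data$agent %in% agents)
  df <- tidyr::pivot_longer(df[, c("t", "agent", vars)], dplyr::all_of(vars),
                            names_to = "variable", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$value, colour = .data$agent)) +
    shade_disruption(object) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time-step", y = NULL,
                  title = sprintf("Scenario %s (%s disruption)",
                                  object$config$scenario, object$disruption$type))
}

#' Plot trust trajectories of a run
#'
#' Trustworthiness each buyer attributes to each supplier over time, with
#' the disruption window shaded.
#'
#' @param run An `sc_run`.
#' @return A ggplot object.
#' @export
plot_trust <- function(run) {
  ggplot2::ggplot(run$trust,
                  ggplot2::aes(.data$t, .data$trust, colour = .data$seller)) +
    shade_disruption(run) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~buyer) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time-step", y = "attributed trustworthiness")
}

#' Plot per-edge order flows of a run
#'
#' @param run An `sc_run`.
#' @param buyer Optional buyer name to restrict to (e.g. `"Trust HC"`).
#' @return A ggplot object.
#' @export
plot_orders <- function(run, buyer = NULL) {
  df <- run$flows
  if (!is.null(buyer)) df <- dplyr::filter(df, .data$buyer %in% !!buyer)
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$order, colour = .data$seller)) +
    shade_disruption(run) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~buyer) +
    ggplot2::labs(x = "time-step", y = "order quantity")
}

#' Plot a delta sweep
#'
#' Window cost per healthcenter as a function of the trust sensitivity
#' factor.
#'
#' @param object An `sc_sweep` from [sweep_delta()].
#' @param echelons Echelons to include (default healthcenters).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sc_sweep <- function(object, echelons = "healthcenter", ...) {
  df <- dplyr::filter(tibble::as_tibble(object), .data$echelon %in% echelons)
  ggplot2::ggplot(df, ggplot2::aes(.data$delta, .data$cost, colour = .data$agent)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(delta), y = "window cost")
}

shade_disruption <- function(run) {
  s <- run$disruption$start
  if (is.na(s)) return(NULL)
  ggplot2::annotate("rect", xmin = s, xmax = s + run$disruption$breadth,
                    ymin = -Inf, ymax = Inf, alpha = 0.12, fill = "red")
}
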